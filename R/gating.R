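# Ensemble statistics of the gating order parameters: windowed pooling,
# wet/dewet classification, 1D distributions with mode detection, 2D
# log-population heat maps and order-parameter correlations.

#' Pool the final window of one or more trajectories
#'
#' Retains, per trajectory, the last `ceil(window_fraction * n_frames)`
#' records (the equilibrated tail, e.g. the last 500 ns of a 2 us run at
#' fraction 0.25) and concatenates across trajectories of one variant.
#'
#' @param series_list an `order_param_series` or list of them, all sharing
#'   one variant label.
#' @param window_fraction fraction in (0, 1] of each trajectory to keep.
#' @return A `pooled_ensemble` (data.frame of pooled records).
#' @export
pool_window <- function(series_list, window_fraction = 0.25) {
  if (inherits(series_list, "order_param_series")) series_list <- list(series_list)
  if (length(series_list) == 0L) stop("no series to pool", call. = FALSE)
  if (!(window_fraction > 0 && window_fraction <= 1))
    stop("window_fraction must be in (0, 1]", call. = FALSE)
  labs <- unique(unlist(lapply(series_list, function(s) unique(s$variant))))
  if (length(labs) != 1L)
    stop("pool_window requires a single variant; got: ",
         paste(labs, collapse = ", "), call. = FALSE)
  kept <- lapply(series_list, function(s) {
    n <- nrow(s)
    k <- ceiling(window_fraction * n)
    as.data.frame(s)[seq(n - k + 1L, n), , drop = FALSE]
  })
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  attr(out, "chains") <- attr(series_list[[1L]], "chains")
  attr(out, "pairs") <- attr(series_list[[1L]], "pairs")
  attr(out, "window_fraction") <- window_fraction
  attr(out, "n_trajectories") <- length(series_list)
  class(out) <- c("pooled_ensemble", "data.frame")
  out
}

#' Classify cavity hydration
#'
#' Wet iff the water count is at or above the threshold (the "red line"
#' separating wetted from dewetted cavities); boundary inclusive.
#'
#' @param n_waters integer vector of cavity water counts.
#' @param wet_threshold threshold count, >= 0.
#' @return factor with levels `dewet`, `wet`.
#' @export
classify_hydration <- function(n_waters, wet_threshold) {
  stopifnot(wet_threshold >= 0)
  factor(ifelse(n_waters >= wet_threshold, "wet", "dewet"),
         levels = c("dewet", "wet"))
}

#' Normalised 1D histogram
#'
#' Fixed-width bins over `range` (taken from the data when omitted, snapped
#' to multiples of `bin_width`); bin masses sum to one. Angular observables
#' use `circular = TRUE` with the fixed range `[0, 360)`.
#'
#' @param values numeric vector (>= 1 value).
#' @param bin_width bin width, > 0.
#' @param range length-2 numeric, optional.
#' @param circular treat the axis as periodic over `[0, 360)`.
#' @return list of class `op_histogram`: `edges`, `mids`, `mass`, `n`,
#'   `circular`.
#' @export
histogram_1d <- function(values, bin_width, range = NULL, circular = FALSE) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values to bin", call. = FALSE)
  if (!(bin_width > 0)) stop("bin_width must be positive", call. = FALSE)
  if (circular) {
    values <- values %% 360
    range <- c(0, 360)
  } else if (is.null(range)) {
    lo <- floor(min(values) / bin_width) * bin_width
    hi <- ceiling(max(values) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    range <- c(lo, hi)
  }
  nb <- max(1L, as.integer(ceiling((range[2L] - range[1L]) / bin_width - 1e-9)))
  edges <- range[1L] + bin_width * (0:nb)
  idx <- pmin(pmax(floor((values - range[1L]) / bin_width) + 1L, 1L), nb)
  counts <- tabulate(idx, nbins = nb)
  structure(list(edges = edges, mids = (edges[-1L] + edges[-(nb + 1L)]) / 2,
                 mass = counts / length(values), n = length(values),
                 circular = circular),
            class = "op_histogram")
}

#' @noRd
moving_average <- function(x, window, circular = FALSE) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  h <- (window - 1L) %/% 2L
  n <- length(x)
  if (circular) {
    xp <- c(x[(n - h + 1L):n], x, x[1L:h])
    as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))[(h + 1L):(h + n)]
  } else {
    out <- numeric(n)
    for (i in seq_len(n)) {
      j <- max(1L, i - h):min(n, i + h)
      out[i] <- mean(x[j])
    }
    out
  }
}

#' Detect distribution modes
#'
#' Local maxima of the moving-average-smoothed bin masses with prominence at
#' least `prominence_frac` of the global maximum; circular histograms are
#' smoothed and compared with wrap-around. A flat distribution has no modes.
#'
#' @param h an [histogram_1d()] result.
#' @param smooth_window moving-average window in bins (forced odd).
#' @param prominence_frac minimum peak height as fraction of the max.
#' @return data.frame of class `mode_set` with `location` (bin centre,
#'   ascending) and `prominence` (fraction of global max).
#' @export
find_modes <- function(h, smooth_window = 5L, prominence_frac = 0.1) {
  stopifnot(inherits(h, "op_histogram"))
  m <- moving_average(h$mass, smooth_window, circular = h$circular)
  n <- length(m)
  empty <- data.frame(location = numeric(0L), prominence = numeric(0L))
  class(empty) <- c("mode_set", "data.frame")
  if (n == 0L || max(m) - min(m) < 1e-15) return(empty)
  left <- if (h$circular) m[c(n, seq_len(n - 1L))] else c(-Inf, m[-n])
  right <- if (h$circular) m[c(seq_len(n - 1L) + 1L, 1L)] else c(m[-1L], -Inf)
  is_peak <- m > left & m >= right
  keep <- is_peak & m >= prominence_frac * max(m)
  if (!any(keep)) return(empty)
  out <- data.frame(location = h$mids[keep], prominence = m[keep] / max(m))
  out <- out[order(out$location), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mode_set", "data.frame")
  out
}

#' Suggest a wet/dewet threshold from pooled water counts
#'
#' Midpoint between the two most prominent modes of the count distribution
#' when it is genuinely bimodal (modes more than 5 waters apart with a
#' population valley between them); a fixed fallback of 10 waters
#' otherwise, so a fully wet or fully dewet ensemble is never split on
#' sampling noise around its single peak.
#'
#' @param n_waters pooled cavity water counts.
#' @param fallback threshold used when the distribution is not bimodal.
#' @return numeric threshold.
#' @export
suggest_wet_threshold <- function(n_waters, fallback = 10) {
  h <- histogram_1d(n_waters, bin_width = 1)
  modes <- find_modes(h, smooth_window = 5L, prominence_frac = 0.1)
  if (nrow(modes) < 2L) return(fallback)
  top2 <- sort(modes[order(-modes$prominence)[1:2], "location"])
  if (diff(top2) <= 5) return(fallback)
  sm <- moving_average(h$mass, 5L)
  between <- h$mids > top2[1L] & h$mids < top2[2L]
  peak_lo <- min(sm[match(top2, h$mids)])
  if (!any(between) || min(sm[between]) > 0.5 * peak_lo) return(fallback)
  mean(top2)
}

#' 2D population heat map with correlation
#'
#' Bins paired observables into a counts matrix and computes the
#' correlation (Pearson by default) on the raw, unbinned pairs. The log10
#' scale of the published population maps is applied only at rendering
#' ([plot.heatmap2d()]), with empty bins masked.
#'
#' @param x_values,y_values equal-length paired observables.
#' @param x_edges,y_edges ascending bin boundaries covering the data.
#' @param method correlation method, `"pearson"` or `"spearman"`.
#' @return list of class `heatmap2d`: `x_edges`, `y_edges`, `counts`,
#'   `pearson_r` (NA when a marginal is degenerate), `n_points`.
#' @export
heatmap_log2d <- function(x_values, y_values, x_edges, y_edges,
                          method = "pearson") {
  stopifnot(length(x_values) == length(y_values))
  ok <- is.finite(x_values) & is.finite(y_values)
  x <- x_values[ok]; y <- y_values[ok]
  nx <- length(x_edges) - 1L; ny <- length(y_edges) - 1L
  ix <- pmin(pmax(findInterval(x, x_edges, rightmost.closed = TRUE), 1L), nx)
  iy <- pmin(pmax(findInterval(y, y_edges, rightmost.closed = TRUE), 1L), ny)
  counts <- matrix(0L, nx, ny)
  tab <- table(factor(ix, levels = seq_len(nx)), factor(iy, levels = seq_len(ny)))
  counts[] <- as.integer(tab)
  r <- if (length(x) >= 2L && stats::sd(x) > 0 && stats::sd(y) > 0)
    stats::cor(x, y, method = method) else NA_real_
  structure(list(x_edges = x_edges, y_edges = y_edges, counts = counts,
                 pearson_r = r, n_points = length(x)),
            class = "heatmap2d")
}

#' @rdname heatmap_log2d
#' @param x a `heatmap2d`.
#' @param ... passed to [graphics::image()].
#' @export
plot.heatmap2d <- function(x, ...) {
  z <- x$counts
  z[z == 0L] <- NA
  graphics::image(x = x$x_edges, y = x$y_edges, z = log10(z),
                  useRaster = TRUE, ...)
  invisible(x)
}

#' @noRd
make_edges <- function(values, width) {
  lo <- floor(min(values) / width) * width
  hi <- ceiling(max(values) / width) * width
  if (hi <= lo) hi <- lo + width
  seq(lo, hi, by = width)
}

# long vectors pairing chain i's dihedral with the (i -> next) distance,
# and the frame's water count replicated per chain
#' @noRd
paired_observables <- function(pooled) {
  chains <- attr(pooled, "chains")
  pairs <- attr(pooled, "pairs")
  dih <- unlist(lapply(paste0("dih_", chains), function(cn) pooled[[cn]]),
                use.names = FALSE)
  dst <- unlist(lapply(pairs, function(cn) pooled[[cn]]), use.names = FALSE)
  wat <- rep(pooled$n_waters, times = length(chains))
  list(dihedral = dih, distance = dst, waters = wat)
}

#' Per-variant gating summary
#'
#' For each variant: the order-parameter correlations (distance vs dihedral
#' pooled over the four inter-subunit pairs, and water count vs dihedral),
#' hydration occupancy under the configured or auto-detected wet threshold,
#' and the detected distance and dihedral modes. Correlations are computed
#' on ensembles pooled over trajectories (set `config$per_trajectory` to
#' average per-trajectory coefficients instead).
#'
#' @param series_list list of `order_param_series` (>= 1 trajectory), any
#'   mix of variants.
#' @param config an `analysis_config`.
#' @return data.frame of class `variant_report`, one row per variant.
#' @export
variant_report <- function(series_list, config = default_config()) {
  if (inherits(series_list, "order_param_series")) series_list <- list(series_list)
  labs <- vapply(series_list, function(s) unique(s$variant)[1L], character(1L))
  rows <- lapply(unique(labs), function(v) {
    pooled <- pool_window(series_list[labs == v], config$window_fraction)
    ob <- paired_observables(pooled)
    thr <- if (identical(config$wet_threshold, "auto"))
      suggest_wet_threshold(pooled$n_waters) else config$wet_threshold
    hyd <- classify_hydration(pooled$n_waters, thr)
    corr <- function(a, b) {
      if (nrow(pooled) < 2L) return(NA_real_)  # no frame-to-frame variation
      if (isTRUE(config$per_trajectory)) {
        ntraj <- attr(pooled, "n_trajectories")
        # per-trajectory coefficients averaged; pooled is the default route
        per <- vapply(series_list[labs == v], function(s) {
          p1 <- pool_window(list(s), config$window_fraction)
          o1 <- paired_observables(p1)
          stats::cor(o1[[a]], o1[[b]], method = config$correlation)
        }, numeric(1L))
        mean(per, na.rm = TRUE)
      } else if (length(ob[[a]]) >= 2L && stats::sd(ob[[a]]) > 0 &&
                 stats::sd(ob[[b]]) > 0) {
        stats::cor(ob[[a]], ob[[b]], method = config$correlation)
      } else NA_real_
    }
    dmodes <- find_modes(histogram_1d(ob$distance, config$bin_distance),
                         config$smooth_window, config$prominence)
    amodes <- find_modes(histogram_1d(ob$dihedral, config$bin_dihedral,
                                      circular = TRUE),
                         config$smooth_window, config$prominence)
    data.frame(variant = v, n_records = nrow(pooled),
               r_dist_dihedral = corr("distance", "dihedral"),
               r_waters_dihedral = corr("waters", "dihedral"),
               wet_threshold = thr,
               frac_wet = mean(hyd == "wet"),
               distance_modes = paste(round(dmodes$location, 3), collapse = ";"),
               dihedral_modes = paste(round(amodes$location, 3), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("variant_report", "data.frame")
  out
}
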