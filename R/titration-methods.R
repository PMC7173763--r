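# S3 methods for titration_fit objects.

#' @export
print.titration_fit <- function(x, ...) {
  cat("Ensemble titration fit\n")
  cat("  sites:           ", length(x$sites$site_id), "\n")
  cat("  microstates:     ", length(x$subset), "dominant of", x$n_microstates, "\n")
  cat("  structures:      ", x$model$n_structures, "\n")
  cat("  pH grid:         ", min(x$ph), "-", max(x$ph),
      "step", signif(diff(x$ph[1:2]), 3), "\n")
  cat("  temperature:     ", x$model$temperature, "K\n")
  cat("  pKa estimates:\n")
  print(format(stats::setNames(x$pka$pka, x$pka$site_id), digits = 4))
  invisible(x)
}

#' Summarise a titration fit
#'
#' pKa point estimates with the widest (`k = max`) uncertainty band and
#' multi-crossing flags.
#'
#' @param object a `titration_fit`.
#' @param ... unused.
#' @export
summary.titration_fit <- function(object, ...) {
  kmax <- max(object$bands$k)
  b <- object$bands[object$bands$k == kmax, c("site_id", "low", "high")]
  names(b) <- c("site_id", "band_low", "band_high")
  out <- merge(object$pka, b, by = "site_id", sort = FALSE)
  out$band_k <- kmax
  structure(list(table = out, temperature = object$model$temperature,
                 n_structures = object$model$n_structures,
                 scheme = object$uncertainty_scheme),
            class = "summary.titration_fit")
}

#' @export
print.summary.titration_fit <- function(x, ...) {
  cat("Ensemble titration summary (", x$n_structures, " structures, ",
      x$temperature, " K)\n", sep = "")
  cat("uncertainty: ", x$scheme, "\n\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' pKa point estimates of a titration fit
#'
#' @param object a `titration_fit`.
#' @param ... unused.
#' @return named numeric vector of per-site pKa values (NA when the curve
#'   never crosses 0.5 on the grid).
#' @export
coef.titration_fit <- function(object, ...) {
  stats::setNames(object$pka$pka, object$pka$site_id)
}

#' Predict protonation fractions at new pH values
#'
#' @param object a `titration_fit`.
#' @param ph pH values (defaults to the fitted grid).
#' @param ... unused.
#' @return matrix, `length(ph)` x sites.
#' @export
predict.titration_fit <- function(object, ph = object$ph, ...) {
  protonation_fraction(object$model, site = NULL, ph = ph,
                       subset = object$subset)
}

#' Uncertainty band of the pKa estimates
#'
#' The `<E> +/- k sigma` band at a chosen shift multiplier.
#'
#' @param object a `titration_fit`.
#' @param parm site ids (default all).
#' @param level unused (bands are indexed by `k`, not coverage).
#' @param k shift multiplier; must be one of the fitted `ks`.
#' @param ... unused.
#' @return matrix with columns `low`, `high`, one row per site.
#' @export
confint.titration_fit <- function(object, parm = NULL, level = NULL, k = 1.0, ...) {
  b <- object$bands[abs(object$bands$k - k) < 1e-9, , drop = FALSE]
  if (nrow(b) == 0L)
    stop("k = ", k, " was not fitted; available: ",
         paste(unique(object$bands$k), collapse = ", "), call. = FALSE)
  if (!is.null(parm)) b <- b[b$site_id %in% parm, , drop = FALSE]
  m <- as.matrix(b[, c("low", "high")])
  rownames(m) <- b$site_id
  m
}

#' Plot titration curves
#'
#' Protonation fraction against pH per site, with the pKa crossing marked
#' and the `k = 1` uncertainty band shaded on the pH axis.
#'
#' @param x a `titration_fit`.
#' @param sites site ids to draw (default all).
#' @param band_k band multiplier to shade, or `NA` for none.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.titration_fit <- function(x, sites = x$sites$site_id, band_k = 1.0, ...) {
  th <- x$theta[, sites, drop = FALSE]
  graphics::matplot(x$ph, th, type = "l", lty = 1,
                    xlab = "pH", ylab = expression(theta(pH)),
                    ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, col = "grey60", lty = 3)
  cols <- seq_along(sites)
  if (!is.na(band_k) && any(abs(x$bands$k - band_k) < 1e-9)) {
    for (i in seq_along(sites)) {
      b <- x$bands[x$bands$site_id == sites[i] &
                     abs(x$bands$k - band_k) < 1e-9, ]
      if (nrow(b) == 1L && is.finite(b$low) && is.finite(b$high))
        graphics::segments(b$low, 0.5, b$high, 0.5, col = cols[i], lwd = 3)
    }
  }
  pk <- coef(x)[sites]
  ok <- is.finite(pk)
  if (any(ok)) graphics::points(pk[ok], rep(0.5, sum(ok)), col = cols[ok], pch = 19)
  graphics::legend("topright", legend = sites, col = cols, lty = 1, bty = "n")
  invisible(x)
}
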