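# Protonation-microstate energy tables.
#
# An energy_table stores E(microstate, structure) in kcal/mol: a binary
# microstate matrix (rows = microstates, columns = titratable sites), a
# vector of structure labels, and the dense energy matrix. This is the
# artifact's substitute for per-state continuum-electrostatics/force-field
# energies evaluated on ensemble structures.

#' Construct an energy table
#'
#' @param microstates integer matrix (0/1), one row per protonation
#'   microstate, one named column per titratable site.
#' @param structures character vector of structure labels.
#' @param energy numeric matrix, `nrow(microstates)` x `length(structures)`,
#'   kcal/mol.
#' @return An object of class `energy_table`.
#' @export
energy_table <- function(microstates, structures, energy) {
  microstates <- as.matrix(microstates)
  storage.mode(microstates) <- "integer"
  if (is.null(colnames(microstates)))
    stop("microstate matrix must have site names as column names", call. = FALSE)
  if (!all(microstates %in% c(0L, 1L)))
    stop("microstate entries must be 0 or 1", call. = FALSE)
  keys <- apply(microstates, 1L, paste, collapse = "")
  if (anyDuplicated(keys))
    stop("duplicate microstate vectors", call. = FALSE)
  energy <- as.matrix(energy)
  if (nrow(energy) != nrow(microstates) || ncol(energy) != length(structures))
    stop("energy matrix dimensions do not match microstates x structures",
         call. = FALSE)
  if (any(!is.finite(energy)))
    stop("non-finite energies", call. = FALSE)
  rownames(microstates) <- rownames(energy) <- keys
  colnames(energy) <- as.character(structures)
  structure(list(sites = colnames(microstates),
                 microstates = microstates,
                 structures = as.character(structures),
                 energy = energy),
            class = "energy_table")
}

#' @export
print.energy_table <- function(x, ...) {
  cat("energy table:", nrow(x$microstates), "microstates x",
      length(x$structures), "structures over", length(x$sites), "sites\n")
  cat("sites:", paste(x$sites, collapse = ", "), "\n")
  invisible(x)
}

#' Read a microstate energy table from CSV
#'
#' The CSV must contain one 0/1 column per titratable site, a `structure`
#' label column and an `energy` column (kcal/mol unless `energy_unit`
#' says otherwise). Every microstate must be present for every structure;
#' duplicated (microstate, structure) rows are rejected.
#'
#' @param path CSV path (header row mandatory).
#' @param energy_unit `"kcal/mol"` (default) or `"kJ/mol"`; kJ values are
#'   converted on read (divided by 4.184).
#' @return An [energy_table()].
#' @export
read_energy_table <- function(path, energy_unit = c("kcal/mol", "kJ/mol")) {
  energy_unit <- match.arg(energy_unit)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("structure", "energy")
  if (!all(need %in% names(df)))
    stop("energy CSV must have 'structure' and 'energy' columns", call. = FALSE)
  sites <- setdiff(names(df), need)
  if (length(sites) == 0L) stop("no site columns in energy CSV", call. = FALSE)
  sm <- as.matrix(df[sites])
  if (!all(sm %in% c(0, 1)))
    stop("non-binary site entry in energy CSV (sites must be 0/1)", call. = FALSE)
  storage.mode(sm) <- "integer"
  key <- apply(sm, 1L, paste, collapse = "")
  pair <- paste(key, df$structure, sep = "@")
  if (anyDuplicated(pair))
    stop("duplicated (microstate, structure) row in energy CSV: ",
         pair[anyDuplicated(pair)], call. = FALSE)
  ukey <- unique(key)
  ustr <- unique(as.character(df$structure))
  want <- as.vector(outer(ukey, ustr, paste, sep = "@"))
  missing <- setdiff(want, pair)
  if (length(missing) > 0L)
    stop("incomplete energy table; missing combinations: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) " ..." else "", call. = FALSE)
  e <- matrix(NA_real_, length(ukey), length(ustr),
              dimnames = list(ukey, ustr))
  e[cbind(match(key, ukey), match(as.character(df$structure), ustr))] <- df$energy
  if (energy_unit == "kJ/mol") e <- e / 4.184
  ms <- sm[match(ukey, key), , drop = FALSE]
  colnames(ms) <- sites
  energy_table(ms, ustr, e)
}

#' Write an energy table as CSV
#'
#' Long format matching [read_energy_table()]: one row per
#' (microstate, structure).
#'
#' @param tab an [energy_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(tab, path) {
  stopifnot(inherits(tab, "energy_table"))
  m <- nrow(tab$microstates); k <- length(tab$structures)
  df <- as.data.frame(tab$microstates[rep(seq_len(m), times = k), , drop = FALSE])
  names(df) <- tab$sites
  df$structure <- rep(tab$structures, each = m)
  df$energy <- as.vector(tab$energy)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Enumerate all protonation microstates over a site set
#'
#' @param sites character vector of site ids (at most 20: exact enumeration).
#' @return 0/1 integer matrix with `2^length(sites)` rows.
#' @export
enumerate_microstates <- function(sites) {
  n <- length(sites)
  if (n > 20L)
    stop("exact enumeration limited to 20 sites; Monte-Carlo titration ",
         "sampling is out of scope", call. = FALSE)
  m <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  storage.mode(m) <- "integer"
  colnames(m) <- sites
  m
}
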