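#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Harmonic mean
#' @param x positive numeric vector
#' @return harmonic mean of `x`
#' @keywords internal
#' @noRd
harmonic_mean <- function(x) {
  stopifnot(all(x > 0))
  length(x) / sum(1 / x)
}

#' Dirichlet draws via gamma normalization
#' @keywords internal
#' @noRd
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Oriented z-score: higher output always means "more of the flagged
#' direction". Constant components return 0 for all entries.
#' @keywords internal
#' @noRd
oriented_z <- function(x, higher_is_more = TRUE) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(ifelse(is.na(x), NA_real_, 0))
  z <- (x - mean(x, na.rm = TRUE)) / s
  if (higher_is_more) z else -z
}

#' Write a tabular output with a provenance header
#'
#' All pipeline stages emit TSV with commented header lines recording the
#' package version, the seed in force and a hash of the configuration, so
#' any output can be traced back to the run that produced it.
#'
#' @param df data frame to write
#' @param path output path
#' @param seed integer seed recorded in the header (NA if the stage is
#'   deterministic)
#' @param config optional list; a short hash of its serialized form is
#'   recorded
#' @return `path`, invisibly
#' @export
write_provenance_tsv <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# streamscape %s",
                     as.character(utils::packageVersion("streamscape"))), con)
  writeLines(sprintf("# seed: %s", as.character(seed)), con)
  writeLines(sprintf("# config_hash: %s", config_hash(config)), con)
  write.table(format(df, trim = TRUE, digits = 10), con,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
#' @noRd
config_hash <- function(config) {
  if (is.null(config)) return("none")
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  # small rolling hash; provenance only, not cryptographic
  h <- 0
  for (v in utf8ToInt(txt)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

#' Read a tabular output written by [write_provenance_tsv()]
#' @param path file path
#' @return data frame (provenance comments skipped)
#' @export
read_provenance_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Read a run configuration file (YAML or JSON)
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file
#' @return named list; a `seed` entry is required
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$seed)) stop("run configuration must include a 'seed'")
  cfg
}
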