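#' Score and rank candidate recipient populations
#'
#' Concretizes the qualitative recipient criteria for managed gene flow:
#' a population most in need of incoming variation has low neutral
#' diversity (Hs), low effective size, high isolation, high inbreeding
#' and high deleterious variation. Each available component is converted
#' to a within-dataset z-score oriented so that higher always means
#' "more in need", and the recipient-risk score is the weighted mean of
#' the non-missing components (weights renormalized). Ranks break ties
#' by population label.
#'
#' @param metrics data frame keyed by `population` with any of the
#'   columns `hs`, `ne`, `isolation` (e.g. median linearized FST to
#'   same-metapopulation neighbours), `pct_roh` (mean percent of genome
#'   in runs of homozygosity), `load` (mean deleterious proportion)
#' @param weights named weights over those components (default equal)
#' @return data frame of class `priority_report`, ranked by descending
#'   recipient risk, with per-component z-scores
#' @export
score_recipients <- function(metrics,
                             weights = c(hs = 1, ne = 1, isolation = 1,
                                         pct_roh = 1, load = 1)) {
  stopifnot(!is.null(metrics$population))
  orient <- c(hs = FALSE, ne = FALSE,     # low diversity/size -> high risk
              isolation = TRUE, pct_roh = TRUE, load = TRUE)
  comps <- intersect(names(orient), names(metrics))
  if (!length(comps)) stop("no recognised component columns in metrics")
  if (all(weights[comps] == 0, na.rm = TRUE)) stop("all weights are zero")
  Z <- sapply(comps, function(cc) oriented_z(metrics[[cc]], orient[[cc]]))
  if (nrow(metrics) == 1) Z <- rbind(Z)
  W <- matrix(rep(weights[comps], each = nrow(metrics)), nrow(metrics))
  W[is.na(Z)] <- 0
  if (any(rowSums(abs(W)) == 0)) {
    drop <- rowSums(abs(W)) == 0
    warning("population(s) with all components missing excluded: ",
            paste(metrics$population[drop], collapse = ", "))
  }
  score <- rowSums(Z * W, na.rm = TRUE) / rowSums(abs(W))
  out <- data.frame(population = metrics$population,
                    recipient_risk = score, stringsAsFactors = FALSE)
  colnames(Z) <- paste0("z_", comps)
  out <- cbind(out, as.data.frame(Z))
  out <- out[is.finite(out$recipient_risk), , drop = FALSE]
  out <- out[order(-out$recipient_risk, out$population), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("priority_report", "data.frame")
  out
}

#' Score and rank candidate donor populations for a given recipient
#'
#' Safer donors have low differentiation from the recipient, low
#' divergence time, few structural-variant differences relative to the
#' recipient, high neutral diversity and low genetic load. Components
#' are oriented z-scores aggregated by weighted mean, as in
#' [score_recipients()]. Donors in the recipient's own metapopulation
#' are flagged as the default safest class.
#'
#' @param metrics data frame keyed by `population` with columns among
#'   `fst_to_recipient`, `divergence_time`, `sv_differential`, `hs`,
#'   `load`, and optionally `metapopulation`
#' @param recipient population label of the recipient (must appear in
#'   `metrics`; it is excluded from the candidate set)
#' @param weights named weights (default equal)
#' @return data frame of class `priority_report`, ranked by descending
#'   compatibility, with a `same_metapopulation` flag when metapopulation
#'   labels are available
#' @export
score_donors <- function(metrics, recipient,
                         weights = c(fst_to_recipient = 1,
                                     divergence_time = 1,
                                     sv_differential = 1, hs = 1, load = 1)) {
  stopifnot(!is.null(metrics$population))
  if (!recipient %in% metrics$population) {
    stop("recipient '", recipient, "' absent from metrics")
  }
  rec <- metrics[metrics$population == recipient, , drop = FALSE]
  cand <- metrics[metrics$population != recipient, , drop = FALSE]
  if (nrow(cand) == 0) stop("no candidate donors")
  orient <- c(fst_to_recipient = FALSE, divergence_time = FALSE,
              sv_differential = FALSE, hs = TRUE, load = FALSE)
  comps <- intersect(names(orient), names(cand))
  if (!length(comps)) stop("no recognised component columns in metrics")
  if (all(weights[comps] == 0, na.rm = TRUE)) stop("all weights are zero")
  Z <- sapply(comps, function(cc) oriented_z(cand[[cc]], orient[[cc]]))
  if (nrow(cand) == 1) Z <- rbind(Z)
  W <- matrix(rep(weights[comps], each = nrow(cand)), nrow(cand))
  W[is.na(Z)] <- 0
  score <- rowSums(Z * W, na.rm = TRUE) / rowSums(abs(W))
  out <- data.frame(population = cand$population, recipient = recipient,
                    compatibility = score, stringsAsFactors = FALSE)
  if (!is.null(cand$metapopulation) && !is.null(rec$metapopulation)) {
    out$same_metapopulation <- cand$metapopulation == rec$metapopulation
  }
  colnames(Z) <- paste0("z_", comps)
  out <- cbind(out, as.data.frame(Z))
  out <- out[is.finite(out$compatibility), , drop = FALSE]
  out <- out[order(-out$compatibility, out$population), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("priority_report", "data.frame")
  out
}
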