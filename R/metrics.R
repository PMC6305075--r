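#' ROC AUC by the Mann-Whitney statistic
#'
#' The probability that a randomly chosen active outscores a randomly chosen
#' decoy, with ties counted half. Computed exactly from ranks.
#'
#' @param scores numeric screening scores.
#' @param is_active logical (or 0/1) activity labels.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, is_active) {
  is_active <- as.logical(is_active)
  stopifnot(length(scores) == length(is_active))
  n_act <- sum(is_active)
  n_dec <- sum(!is_active)
  if (n_act == 0 || n_dec == 0) {
    stop("AUC requires at least one active and one decoy")
  }
  r <- rank(scores)  # midranks handle ties as half-wins
  (sum(r[is_active]) - n_act * (n_act + 1) / 2) / (n_act * n_dec)
}

#' Enrichment factor at a screened fraction
#'
#' `EF = (Hits_sampled / N_sampled) * (N_total / Hits_total)`, where
#' `N_sampled = ceiling(fraction * N_total)` molecules are taken from the top
#' of the score ranking (ties broken by ligand id for determinism) and
#' `Hits_sampled` of them are active. EF is 1 in expectation for random
#' ranking and equals 1 exactly at fraction 1.
#'
#' @param scores numeric screening scores.
#' @param is_active logical activity labels.
#' @param fraction screened fraction in `(0, 1]`.
#' @param ligand_id optional ids used for deterministic tie-breaking.
#' @return the enrichment factor, with the contingency counts
#'   (`Hits_sampled`, `N_sampled`, `Hits_total`, `N_total`) as attributes.
#' @export
compute_ef <- function(scores, is_active, fraction, ligand_id = NULL) {
  is_active <- as.logical(is_active)
  stopifnot(length(scores) == length(is_active))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n_total <- length(scores)
  hits_total <- sum(is_active)
  if (n_total < 1) stop("empty score list")
  if (hits_total == 0) stop("EF is undefined without actives")
  if (is.null(ligand_id)) ligand_id <- as.character(seq_along(scores))
  ord <- order(-scores, ligand_id)
  n_sampled <- ceiling(fraction * n_total)
  hits_sampled <- sum(is_active[ord[seq_len(n_sampled)]])
  ef <- (hits_sampled / n_sampled) * (n_total / hits_total)
  attr(ef, "counts") <- c(Hits_sampled = hits_sampled, N_sampled = n_sampled,
                          Hits_total = hits_total, N_total = n_total)
  ef
}

#' Evaluate a virtual screen
#'
#' Joins screening scores with activity labels and reports ROC AUC and
#' enrichment factors at the requested fractions.
#'
#' @param scores data frame from [screen_library()] (ligand_id, fit_score),
#'   or a named numeric vector of scores.
#' @param labels data frame with columns `ligand_id` and `is_active`.
#' @param fractions numeric vector of screened fractions.
#' @return an `enrichment_report`: list with `auc`, `ef` (data frame:
#'   fraction, ef, Hits_sampled, N_sampled), `Hits_total`, `N_total`.
#' @export
evaluate_screen <- function(scores, labels, fractions = c(0.01, 0.02, 0.05)) {
  if (is.numeric(scores) && !is.null(names(scores))) {
    scores <- data.frame(ligand_id = names(scores), fit_score = unname(scores),
                         stringsAsFactors = FALSE)
  }
  m <- match(scores$ligand_id, labels$ligand_id)
  if (any(is.na(m))) stop("labels missing for: ",
                          paste(scores$ligand_id[is.na(m)][1:3], collapse = ", "))
  act <- as.logical(labels$is_active[m])
  auc <- compute_auc(scores$fit_score, act)
  ef_rows <- lapply(fractions, function(fr) {
    ef <- compute_ef(scores$fit_score, act, fr, scores$ligand_id)
    counts <- attr(ef, "counts")
    data.frame(fraction = fr, ef = as.numeric(ef),
               Hits_sampled = counts["Hits_sampled"],
               N_sampled = counts["N_sampled"])
  })
  structure(list(auc = auc, ef = rownames_reset(do.call(rbind, ef_rows)),
                 Hits_total = sum(act), N_total = length(act)),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("<enrichment_report> %d actives / %d molecules; AUC = %.3f\n",
              x$Hits_total, x$N_total, x$auc))
  for (i in seq_len(nrow(x$ef))) {
    cat(sprintf("  EF@%g%% = %.2f (%d of %d sampled)\n",
                100 * x$ef$fraction[i], x$ef$ef[i], x$ef$Hits_sampled[i],
                x$ef$N_sampled[i]))
  }
  invisible(x)
}

#' @rdname evaluate_screen
#' @param report an `enrichment_report`.
#' @param file output path.
#' @export
write_report <- function(report, file) {
  jsonlite::write_json(list(auc = report$auc, ef = report$ef,
                            Hits_total = report$Hits_total,
                            N_total = report$N_total),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
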