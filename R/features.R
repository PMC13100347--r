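.clinical_fields <- c("er_status", "er_percent", "pr_status", "pr_percent",
                      "cep17", "her2_cep17_ratio")

#' Assemble the 99-dimensional per-compartment feature vector
#'
#' Concatenates, in fixed documented order, the 91 SNA features of the
#' compartment's tissue graph, the compartment's 2 DLPS values (mean
#' and standard deviation of tile response scores; (0, 0) when the
#' compartment had no tiles), and the 6 shared clinical variables
#' (ER/PR status and percentage, CEP17, HER2/CEP17 ratio).
#'
#' @param sna Named 91-vector from \code{\link{extract_sna_features}}.
#' @param dlps Named 10-vector from \code{\link{aggregate_dlps}} (or
#'   \code{NULL} for zero DLPS with a missing flag).
#' @param clinical Named vector / one-row data frame with the 6
#'   clinical fields.
#' @param compartment Compartment whose DLPS pair is used.
#' @return Named numeric vector of length 99 with attribute
#'   \code{dlps_missing}.
#' @export
assemble_features <- function(sna, dlps, clinical, compartment) {
  stopifnot(length(sna) == 91L)
  if (is.data.frame(clinical)) clinical <- unlist(clinical[1L, ])
  miss <- setdiff(.clinical_fields, names(clinical))
  if (length(miss) > 0L) {
    stop("missing clinical field(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(dlps)) {
    dl <- c(0, 0)
    dlps_missing <- TRUE
  } else {
    dl <- unname(dlps[paste0(compartment, c("_mean", "_sd"))])
    dlps_missing <- compartment %in% attr(dlps, "missing")
  }
  out <- c(as.numeric(sna), dl,
           as.numeric(clinical[.clinical_fields]))
  names(out) <- patient_feature_names()
  stopifnot(length(out) == 99L)
  attr(out, "dlps_missing") <- dlps_missing
  out
}

#' Names of the 99 per-compartment feature slots, in order
#'
#' @return Character vector of length 99: the 91 SNA names, then
#'   \code{DLPS_mean}, \code{DLPS_sd}, then the 6 clinical fields.
#' @export
patient_feature_names <- function() {
  c(sna_feature_names(), "DLPS_mean", "DLPS_sd", .clinical_fields)
}

#' SNA feature matrix for a whole cohort
#'
#' Builds the compartment's tissue graph for every patient and stacks
#' the 91-dimensional SNA vectors.
#'
#' @param cohort A \code{tme_cohort}.
#' @param compartment Compartment name.
#' @param gparams A \code{\link{graph_params}}.
#' @param sparams An \code{\link{sna_params}}.
#' @return Numeric matrix (patients x 91) with attribute \code{valid}
#'   (logical per patient; FALSE for empty graphs).
#' @export
cohort_sna_matrix <- function(cohort, compartment,
                              gparams = graph_params(),
                              sparams = sna_params()) {
  n <- length(cohort$patients)
  X <- matrix(0, n, 91L, dimnames = list(names(cohort$patients),
                                         sna_feature_names()))
  valid <- logical(n)
  for (i in seq_len(n)) {
    g <- build_tissue_graph(cohort$patients[[i]]$tta, compartment, gparams)
    v <- extract_sna_features(g, sparams)
    X[i, ] <- v
    valid[i] <- isTRUE(attr(v, "valid"))
  }
  attr(X, "valid") <- valid
  X
}

#' Clinical covariate matrix for a cohort
#'
#' @param cohort A \code{tme_cohort}.
#' @return Numeric matrix (patients x 6) of the shared clinical
#'   variables.
#' @export
cohort_clinical_matrix <- function(cohort) {
  clin <- cohort_clinical(cohort)
  X <- as.matrix(clin[, .clinical_fields])
  rownames(X) <- clin$patient_id
  X
}
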