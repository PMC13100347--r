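#' Synthetic-cohort configuration
#'
#' Parameters of the synthetic-cohort generator, which emulates the
#' structure the pipeline consumes: tile-level tissue maps whose TIL
#' clustering and density differ by response group, class-conditional
#' Gaussian tile embeddings, and clinical covariates with a
#' group-shifted HER2/CEP17 ratio. Per-group parameters are length-2
#' vectors ordered (non-pCR, pCR). Defaults encode the study
#' conditions: responders carry a heavier, more tightly clustered TIL
#' infiltrate (smaller \code{cluster_scale}), which is the planted
#' spatial effect the graph features are meant to recover, and a
#' higher HER2/CEP17 ratio.
#'
#' @param grid_rows,grid_cols Tile-grid dimensions.
#' @param tumor_seed_count Number of tumor discs.
#' @param tumor_disc_radius Disc radius in tiles.
#' @param stroma_band Width (tiles) of the stromal band around tumor.
#' @param itil_rate,stil_rate Per-group fractions of eligible
#'   tumor/stroma tiles converted to iTIL/sTIL tiles.
#' @param cluster_scale Per-group Gaussian cluster scale (tiles) of the
#'   TIL placement process; small values give tight clusters.
#' @param necrosis_rate Fraction of tumor tiles converted to necrosis.
#' @param embedding_dim Embedding dimension per tile.
#' @param embedding_effect Per-group mean shift (in noise SD units)
#'   between classes in embedding space, applied along a fixed random
#'   direction per compartment.
#' @param clinical_effects List of clinical generator parameters:
#'   \code{er_prev}, \code{pr_prev} (per-group positivity),
#'   \code{ratio_meanlog}, \code{ratio_sdlog}, \code{ratio_shift}
#'   (added to the pCR group's HER2/CEP17 log-mean),
#'   \code{cep17_meanlog}, \code{cep17_sdlog}.
#' @param prevalence pCR proportion.
#' @param seed Base seed.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(grid_rows = 60L, grid_cols = 60L,
                       tumor_seed_count = 1L, tumor_disc_radius = 12,
                       stroma_band = 8,
                       itil_rate = c(0.04, 0.14),
                       stil_rate = c(0.06, 0.25),
                       cluster_scale = c(7, 1.5),
                       necrosis_rate = 0.04,
                       embedding_dim = 1024L,
                       embedding_effect = 0.5,
                       clinical_effects = list(
                         er_prev = c(0.80, 0.82),
                         pr_prev = c(0.76, 0.79),
                         ratio_meanlog = log(4.0), ratio_sdlog = 0.5,
                         ratio_shift = 0.4,
                         cep17_meanlog = log(2.2), cep17_sdlog = 0.3),
                       prevalence = 0.42, seed = 1L) {
  stopifnot(grid_rows >= 10L, grid_cols >= 10L,
            all(itil_rate >= 0), all(stil_rate >= 0),
            all(itil_rate <= 1), all(stil_rate <= 1),
            necrosis_rate >= 0, necrosis_rate <= 1,
            prevalence > 0, prevalence < 1)
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 tumor_seed_count = as.integer(tumor_seed_count),
                 tumor_disc_radius = tumor_disc_radius,
                 stroma_band = stroma_band,
                 itil_rate = rep_len(itil_rate, 2L),
                 stil_rate = rep_len(stil_rate, 2L),
                 cluster_scale = rep_len(cluster_scale, 2L),
                 necrosis_rate = necrosis_rate,
                 embedding_dim = as.integer(embedding_dim),
                 embedding_effect = embedding_effect,
                 clinical_effects = clinical_effects,
                 prevalence = prevalence, seed = as.integer(seed)),
            class = "sim_config")
}

# clustered subset selection: pick `target` of the candidate tiles with
# sampling weights given by a Gaussian kernel around Matern-style parent
# points drawn among the candidates
.clustered_pick <- function(coords, target, scale) {
  n <- nrow(coords)
  if (target <= 0L || n == 0L) return(integer(0))
  target <- min(target, n)
  n_parents <- max(1L, round(target / 8))
  parents <- coords[sample.int(n, n_parents), , drop = FALSE]
  d2 <- outer(coords[, 1L], parents[, 1L], "-")^2 +
    outer(coords[, 2L], parents[, 2L], "-")^2
  w <- rowSums(exp(-d2 / (2 * scale^2))) + 1e-4
  sample.int(n, target, prob = w)
}

#' Simulate one TTA-image
#'
#' Tissue is the union of randomly placed tumor discs with a
#' surrounding stromal band. Necrosis is sprinkled inside tumor;
#' iTIL/sTIL tiles are placed by a clustered (parent/offspring) point
#' process whose intensity and cluster scale depend on the response
#' group. Deterministic given \code{seed}.
#'
#' @param config A \code{\link{sim_config}}.
#' @param group 0 (non-pCR) or 1 (pCR).
#' @param seed RNG seed.
#' @param patient_id Identifier stored on the image.
#' @param dispersion_factor Optional per-patient multiplier on the
#'   group's TIL cluster scale (the latent that also drives residual
#'   infiltration size).
#' @return A \code{\link{tta_image}}.
#' @export
simulate_tta_image <- function(config = sim_config(), group = 0L, seed = 1L,
                               patient_id = "sim", dispersion_factor = 1) {
  g <- group + 1L
  set.seed(seed)
  nr <- config$grid_rows; nc <- config$grid_cols
  r <- config$tumor_disc_radius; band <- config$stroma_band
  margin <- r + band + 1
  if (2 * margin >= min(nr, nc)) {
    stop("grid too small for the configured disc radius and stromal band")
  }
  centers <- cbind(stats::runif(config$tumor_seed_count, margin, nr - margin),
                   stats::runif(config$tumor_seed_count, margin, nc - margin))
  rc <- as.matrix(expand.grid(row = seq_len(nr) - 0.5,
                              col = seq_len(nc) - 0.5))
  dmin <- sqrt(Reduce(pmin, lapply(seq_len(nrow(centers)), function(k) {
    (rc[, 1L] - centers[k, 1L])^2 + (rc[, 2L] - centers[k, 2L])^2
  })))
  lab <- rep("B", nr * nc)
  lab[dmin <= r + band] <- "S"
  lab[dmin <= r] <- "T"

  tumor_idx <- which(lab == "T")
  nec <- tumor_idx[stats::runif(length(tumor_idx)) < config$necrosis_rate]
  lab[nec] <- "N"

  scale_g <- config$cluster_scale[g] * dispersion_factor
  tum_left <- which(lab == "T")
  iti <- .clustered_pick(rc[tum_left, , drop = FALSE],
                         round(config$itil_rate[g] * length(tum_left)),
                         scale_g)
  lab[tum_left[iti]] <- "I"
  str_idx <- which(lab == "S")
  sti <- .clustered_pick(rc[str_idx, , drop = FALSE],
                         round(config$stil_rate[g] * length(str_idx)),
                         scale_g)
  lab[str_idx[sti]] <- "L"

  grid <- matrix(lab, nr, nc)  # expand.grid varies row fastest
  tta_image(grid, patient_id,
            preprocess_config())
}

# fixed random unit direction per compartment (independent of patients)
.compartment_directions <- function(dim, seed) {
  set.seed(seed)
  dirs <- lapply(c(TUMOR = 1, STROMA = 2, ITIL = 3, STIL = 4), function(i) {
    v <- stats::rnorm(dim)
    v / sqrt(sum(v^2))
  })
  dirs
}

#' Simulate per-tile embeddings for a TTA-image
#'
#' Each compartment tile receives an isotropic Gaussian embedding
#' (noise SD 1) whose mean is shifted along a fixed random
#' compartment-specific direction by \code{embedding_effect} for the
#' pCR group. Necrosis/background tiles carry no embedding.
#'
#' @param tta A \code{\link{tta_image}}.
#' @param group 0 or 1.
#' @param config A \code{\link{sim_config}}.
#' @param seed RNG seed.
#' @return List with \code{matrix} (tiles x \code{embedding_dim}) and
#'   \code{index} (data frame: \code{row}, \code{col},
#'   \code{compartment}).
#' @export
simulate_embeddings <- function(tta, group, config = sim_config(),
                                seed = 1L) {
  dirs <- .compartment_directions(config$embedding_dim, config$seed + 777L)
  idx <- do.call(rbind, lapply(c("TUMOR", "STROMA", "ITIL", "STIL"),
    function(comp) {
      xy <- extract_compartment(tta, comp)
      if (nrow(xy) == 0L) return(NULL)
      data.frame(row = xy[, 1L], col = xy[, 2L], compartment = comp)
    }))
  if (is.null(idx)) {
    return(list(matrix = matrix(numeric(0), 0L, config$embedding_dim),
                index = data.frame(row = integer(0), col = integer(0),
                                   compartment = character(0))))
  }
  set.seed(seed)
  E <- matrix(stats::rnorm(nrow(idx) * config$embedding_dim),
              nrow(idx), config$embedding_dim)
  if (group == 1L && config$embedding_effect != 0) {
    for (comp in unique(idx$compartment)) {
      rows <- idx$compartment == comp
      E[rows, ] <- E[rows, , drop = FALSE] +
        rep(config$embedding_effect * dirs[[comp]], each = sum(rows))
    }
  }
  list(matrix = E, index = idx)
}

#' Simulate a clinical record
#'
#' ER/PR status are Bernoulli with group-dependent prevalence (the
#' percentage is drawn conditionally on status), CEP17 and the
#' HER2/CEP17 ratio are lognormal with the ratio's log-mean shifted for
#' the pCR group, and residual infiltration size (RIS) is 0 for pCR
#' patients and lognormal otherwise, positively coupled to the
#' patient's TIL-dispersion latent so feature-vs-RIS correlation
#' analyses have recoverable signal.
#'
#' @param group 0 or 1.
#' @param config A \code{\link{sim_config}}.
#' @param seed RNG seed.
#' @param dispersion_factor Per-patient TIL-dispersion latent.
#' @return One-row data frame with columns \code{er_status},
#'   \code{er_percent}, \code{pr_status}, \code{pr_percent},
#'   \code{cep17}, \code{her2_cep17_ratio}, \code{pcr}, \code{ris_cm}.
#' @export
simulate_clinical <- function(group, config = sim_config(), seed = 1L,
                              dispersion_factor = 1) {
  g <- group + 1L
  ce <- config$clinical_effects
  set.seed(seed)
  er <- as.integer(stats::runif(1) < ce$er_prev[g])
  pr <- as.integer(stats::runif(1) < ce$pr_prev[g])
  er_pct <- if (er == 1L) round(stats::rbeta(1, 5, 1.5) * 100) else
    round(stats::runif(1, 0, 9))
  pr_pct <- if (pr == 1L) round(stats::rbeta(1, 4, 2) * 100) else
    round(stats::runif(1, 0, 9))
  cep17 <- stats::rlnorm(1, ce$cep17_meanlog, ce$cep17_sdlog)
  ratio <- stats::rlnorm(1, ce$ratio_meanlog + group * ce$ratio_shift,
                         ce$ratio_sdlog)
  ris <- if (group == 1L) 0 else
    stats::rlnorm(1, log(1.35) + 0.8 * log(dispersion_factor), 0.35)
  data.frame(er_status = er, er_percent = er_pct, pr_status = pr,
             pr_percent = pr_pct, cep17 = cep17, her2_cep17_ratio = ratio,
             pcr = as.integer(group), ris_cm = ris)
}

#' Simulate a full synthetic cohort
#'
#' Draws each patient's response group from the configured prevalence,
#' then composes the TTA-image, embedding and clinical simulators. A
#' per-patient dispersion latent multiplies the group's TIL cluster
#' scale and drives residual infiltration size, linking spatial
#' structure to outcome severity.
#'
#' @param n_patients Number of patients (at least 10).
#' @param config A \code{\link{sim_config}}.
#' @param seed Cohort seed (patient ids embed it, so different seeds
#'   give disjoint ids).
#' @param with_embeddings Generate tile embeddings (memory-heavy for
#'   large grids; enable when DLPS features are needed).
#' @return Object of class \code{tme_cohort}: list of patients (each
#'   with \code{patient_id}, \code{tta}, \code{embeddings},
#'   \code{clinical}, \code{pcr}, \code{ris_cm}) plus the config.
#' @export
simulate_cohort <- function(n_patients = 150L, config = sim_config(),
                            seed = 1L, with_embeddings = FALSE) {
  stopifnot(n_patients >= 10L)
  set.seed(seed)
  groups <- stats::rbinom(n_patients, 1L, config$prevalence)
  sub_seeds <- sample.int(.Machine$integer.max - 10L, n_patients * 3L)
  disp <- exp(stats::rnorm(n_patients, 0, 0.25))
  patients <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%04d_s%d", i, seed)
    tta <- simulate_tta_image(config, groups[i], seed = sub_seeds[i],
                              patient_id = pid,
                              dispersion_factor = disp[i])
    emb <- if (with_embeddings) {
      simulate_embeddings(tta, groups[i], config,
                          seed = sub_seeds[n_patients + i])
    }
    clin <- simulate_clinical(groups[i], config,
                              seed = sub_seeds[2L * n_patients + i],
                              dispersion_factor = disp[i])
    patients[[i]] <- list(patient_id = pid, tta = tta, embeddings = emb,
                          clinical = clin, pcr = groups[i],
                          ris_cm = clin$ris_cm)
  }
  names(patients) <- vapply(patients, `[[`, "", "patient_id")
  structure(list(patients = patients, config = config, seed = seed),
            class = "tme_cohort")
}

#' @export
print.tme_cohort <- function(x, ...) {
  y <- cohort_labels(x)
  cat(sprintf("tme_cohort: %d patients (%d pCR / %d non-pCR), %dx%d grids\n",
              length(y), sum(y), sum(1 - y),
              x$config$grid_rows, x$config$grid_cols))
  invisible(x)
}

#' Patient-level pCR labels of a cohort
#' @param cohort A \code{tme_cohort}.
#' @return Named integer vector (by patient id).
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$patients, function(p) as.integer(p$pcr), integer(1))
}

#' Clinical table of a cohort
#' @param cohort A \code{tme_cohort}.
#' @return Data frame, one row per patient with \code{patient_id}.
#' @export
cohort_clinical <- function(cohort) {
  cbind(patient_id = names(cohort$patients),
        do.call(rbind, lapply(cohort$patients, `[[`, "clinical")),
        row.names = NULL)
}

#' Write a cohort to a directory of plain-text artifacts
#'
#' TTA-images as TSV + JSON sidecars, embeddings (if present) as CSV
#' matrices with index CSVs, and one clinical CSV.
#'
#' @param cohort A \code{tme_cohort}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in cohort$patients) {
    write_tta(p$tta, file.path(dir, paste0(p$patient_id, "_tta.tsv")))
    if (!is.null(p$embeddings)) {
      utils::write.csv(p$embeddings$matrix,
                       file.path(dir, paste0(p$patient_id, "_emb.csv")),
                       row.names = FALSE)
      utils::write.csv(p$embeddings$index,
                       file.path(dir, paste0(p$patient_id, "_emb_index.csv")),
                       row.names = FALSE)
    }
  }
  utils::write.csv(cohort_clinical(cohort), file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by \code{\link{write_cohort}}
#'
#' @param dir Directory path.
#' @return A \code{tme_cohort} (without simulator provenance).
#' @export
read_cohort <- function(dir) {
  clin <- utils::read.csv(file.path(dir, "clinical.csv"))
  patients <- vector("list", nrow(clin))
  for (i in seq_len(nrow(clin))) {
    pid <- clin$patient_id[i]
    tta <- read_tta(file.path(dir, paste0(pid, "_tta.tsv")))
    emb_path <- file.path(dir, paste0(pid, "_emb.csv"))
    emb <- if (file.exists(emb_path)) {
      list(matrix = as.matrix(utils::read.csv(emb_path)),
           index = utils::read.csv(file.path(dir,
                                             paste0(pid, "_emb_index.csv"))))
    }
    if (!is.null(emb)) dimnames(emb$matrix) <- NULL
    patients[[i]] <- list(patient_id = pid, tta = tta, embeddings = emb,
                          clinical = clin[i, setdiff(names(clin),
                                                     "patient_id")],
                          pcr = clin$pcr[i], ris_cm = clin$ris_cm[i])
  }
  names(patients) <- clin$patient_id
  structure(list(patients = patients, config = NULL, seed = NA_integer_),
            class = "tme_cohort")
}
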