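# Synthetic cohort generator.
#
# Emulates the statistical structure the pipeline assumes: a small
# two-class cohort with class-conditional spectral-count distributions for
# a 12-protein serum signature, uninformative noise proteins, zero
# inflation, two technical replicates per subject, and clinical covariates
# with configurable enrollment-order and BMI associations. Fidelity is to
# the signature's class-conditional moments only; true inter-protein
# correlation and distributional families of real serum profiles are
# unknown, so proteins are generated independently.

#' Class-conditional moments of the 12-protein mucositis signature
#'
#' Mean and standard deviation of spectral counts in the GM-negative
#' (class 1) and GM-positive (class 2) groups for the twelve serum
#' proteins most prominent in mucositis prediction.
#'
#' @return data frame with columns `protein_id`, `gene_id`, `mean1`,
#'   `sd1`, `mean2`, `sd2`.
#' @export
default_signature <- function() {
  data.frame(
    protein_id = c("APOA", "APOB", "APOH", "CD14", "CPN2", "FA10",
                   "ITIH2", "MASP1", "PHLD", "PROP", "TETN", "VTNC"),
    gene_id = c("LPA", "APOB", "APOH", "CD14", "CPN2", "F10",
                "ITIH2", "MASP1", "GPLD1", "CFP", "CLEC3B", "VTN"),
    mean1 = c(0.9, 26.2, 6.8, 0.2, 1.6, 0.8, 14.7, 0.2, 1.3, 2.3, 2.7, 5.7),
    sd1   = c(1.2, 30.1, 5.2, 0.5, 1.9, 1.0,  8.7, 0.4, 1.5, 1.1, 1.8, 2.9),
    mean2 = c(5.8, 79.4, 10.9, 1.9, 5.9, 2.9, 32.4, 1.0, 3.5, 3.4, 4.9, 11.6),
    sd2   = c(7.7, 73.2,  6.7, 1.7, 6.0, 3.5, 21.7, 0.9, 3.3, 1.6, 1.1, 6.2))
}

#' Specification of a synthetic cohort
#'
#' @param n_class1 GM-negative subjects (default 9).
#' @param n_class2 GM-positive subjects (default 8).
#' @param signature data frame of per-protein class-conditional moments
#'   ([default_signature()]).
#' @param n_noise_proteins uninformative proteins with no class signal
#'   (default 120, giving 132 proteins in total).
#' @param noise_mean_range range the noise-protein means are drawn from.
#' @param noise_dispersion variance-to-mean ratio of noise counts.
#' @param zero_inflation probability a subject's latent level for a protein
#'   is forced to zero, independent of class.
#' @param effect_scale multiplier on the class-2 minus class-1 difference
#'   of signature means and SDs; 0 erases all class signal, values > 1
#'   exaggerate it.
#' @param replicate_cv coefficient of variation of the multiplicative
#'   replicate-to-replicate perturbation around a subject's latent level.
#' @param signature_cor optional target pairwise correlation among
#'   signature proteins within a class, induced by a shared per-subject
#'   severity factor (default 0: all proteins independent, since only
#'   marginal class-conditional moments are known for the signature).
#'   When positive, class-conditional means and SDs are still preserved
#'   exactly by construction: the factor reallocates part of each
#'   signature protein's variance from independent to shared.
#' @param bmi_association reproduce the positive BMI-mucositis association
#'   (all GM-positive subjects above the BMI cut; default `TRUE`).
#' @param enrollment_association reproduce the late-enrollment mucositis
#'   excess (one GM-positive among the first eight enrolled; default
#'   `TRUE`).
#' @param seed default RNG seed used by [generate_cohort()].
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_class1 = 9L, n_class2 = 8L,
                        signature = default_signature(),
                        n_noise_proteins = 120L,
                        noise_mean_range = c(3, 40),
                        noise_dispersion = 2,
                        zero_inflation = 0.02,
                        effect_scale = 1,
                        replicate_cv = 0.1,
                        signature_cor = 0,
                        bmi_association = TRUE,
                        enrollment_association = TRUE,
                        seed = 1L) {
  stopifnot(n_class1 >= 1L, n_class2 >= 1L,
            all(c(signature$sd1, signature$sd2) >= 0),
            zero_inflation >= 0, zero_inflation <= 1,
            effect_scale >= 0, replicate_cv >= 0,
            signature_cor >= 0, signature_cor < 1,
            noise_dispersion > 0, diff(noise_mean_range) >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

# Moment-matched non-negative integer counts: negative binomial when
# overdispersed (var > mean), Poisson otherwise (a variance below the mean
# cannot be matched by a standard count law; the mismatch is reported by
# the caller).
rcounts <- function(n, mean, sd) {
  if (mean <= 0) return(integer(n))
  v <- sd^2
  if (v > mean) {
    size <- mean^2 / (v - mean)
    stats::rnbinom(n, size = size, mu = mean)
  } else {
    stats::rpois(n, mean)
  }
}

# vectorized form with per-draw means/SDs
rcounts_vec <- function(meanv, sdv) {
  n <- length(meanv)
  out <- integer(n)
  pos <- meanv > 0
  v <- sdv^2
  nb <- pos & v > meanv
  po <- pos & !nb
  if (any(nb))
    out[nb] <- stats::rnbinom(sum(nb), size = meanv[nb]^2 / (v[nb] - meanv[nb]),
                              mu = meanv[nb])
  if (any(po)) out[po] <- stats::rpois(sum(po), meanv[po])
  out
}

#' Generate a synthetic two-replicate cohort
#'
#' For each protein and class, subject latent counts are drawn from a
#' negative binomial moment-matched to the class mean and SD when
#' overdispersed, and from a Poisson with the class mean otherwise (the
#' under-dispersed rows are reported once via a message). Independent zero
#' inflation is applied to the latent levels. Two technical replicates per
#' subject are produced by perturbing the latent level with a
#' multiplicative Gaussian factor of coefficient of variation
#' `replicate_cv` and rounding to a non-negative integer. Clinical
#' covariates (age, BMI, enrollment rank, cancer type, treatment flags)
#' are drawn with class-conditional distributions; with the association
#' switches on (and default class sizes) the dichotomized
#' enrollment-by-mucositis and BMI-by-mucositis tables reproduce the
#' 1-of-8 vs 7-of-9 and 8-of-12 vs 0-of-5 configurations.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer overriding `spec$seed`.
#' @return list with `counts` (long-format raw count table: `subject_id`,
#'   `replicate_id`, `protein_id`, `gene_id`, `count`) and `meta`
#'   (subject metadata including `gm_grade`, `class_label`, `age`, `bmi`,
#'   `enrollment_rank`, flags), plus the `spec` and `seed` used.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_local_seed(seed, generate_cohort_impl(spec, seed))
}

generate_cohort_impl <- function(spec, seed) {
  n1 <- spec$n_class1; n2 <- spec$n_class2; n <- n1 + n2
  cls <- rep(c(1L, 2L), c(n1, n2))
  subjects <- sprintf("S%02d", seq_len(n))

  sig <- spec$signature
  es <- spec$effect_scale
  sig$mean2 <- sig$mean1 + es * (sig$mean2 - sig$mean1)
  sig$sd2 <- pmax(sig$sd1 + es * (sig$sd2 - sig$sd1), 0)
  under <- sig$gene_id[sig$sd1^2 < sig$mean1 | sig$sd2^2 < sig$mean2]
  if (length(under))
    message("Poisson fallback (class variance below mean) for: ",
            paste(unique(under), collapse = ", "))

  k_noise <- spec$n_noise_proteins
  noise_mean <- stats::runif(k_noise, spec$noise_mean_range[1],
                             spec$noise_mean_range[2])
  noise_sd <- sqrt(noise_mean * spec$noise_dispersion)
  prot <- data.frame(
    protein_id = c(sig$protein_id, sprintf("NSP%03d", seq_len(k_noise))),
    gene_id = c(sig$gene_id, sprintf("NOISE%03d", seq_len(k_noise))),
    mean1 = c(sig$mean1, noise_mean), sd1 = c(sig$sd1, noise_sd),
    mean2 = c(sig$mean2, noise_mean), sd2 = c(sig$sd2, noise_sd))

  # shared per-subject severity factor: reallocates part of each signature
  # protein's class-conditional variance from independent to shared,
  # inducing ~signature_cor pairwise correlation while preserving the
  # class means and SDs exactly (up to the count-law's var >= mean floor)
  cv_lat <- 0.5
  rho <- spec$signature_cor
  a <- stats::rlnorm(n, meanlog = -log(1 + cv_lat^2) / 2,
                     sdlog = sqrt(log(1 + cv_lat^2)))
  n_sig <- nrow(sig)
  latent <- matrix(0, n, nrow(prot))
  for (p in seq_len(nrow(prot))) {
    for (cl in 1:2) {
      rows <- cls == cl
      mu <- prot[[paste0("mean", cl)]][p]
      sd_ <- prot[[paste0("sd", cl)]][p]
      if (p <= n_sig && rho > 0 && mu > 0) {
        k <- min(1, sqrt(rho) * sd_ / (mu * cv_lat))
        f <- 1 + k * (a[rows] - 1)
        sd_res <- sqrt(max(sd_^2 - (mu * k * cv_lat)^2, 0) /
                       (1 + (k * cv_lat)^2))
        latent[rows, p] <- rcounts_vec(mu * f, sd_res * f)
      } else {
        latent[rows, p] <- rcounts(sum(rows), mu, sd_)
      }
    }
  }
  if (spec$zero_inflation > 0)
    latent[matrix(stats::runif(length(latent)) < spec$zero_inflation,
                  n, nrow(prot))] <- 0
  reps <- lapply(1:2, function(r) {
    eps <- matrix(stats::rnorm(length(latent), 1, spec$replicate_cv),
                  n, nrow(prot))
    pmax(round(latent * eps), 0)
  })
  counts <- do.call(rbind, lapply(1:2, function(r)
    data.frame(subject_id = rep(subjects, nrow(prot)),
               replicate_id = r,
               protein_id = rep(prot$protein_id, each = n),
               gene_id = rep(prot$gene_id, each = n),
               count = as.integer(as.vector(reps[[r]])))))

  meta <- synth_metadata(cls, subjects, spec)
  list(counts = counts, meta = meta, spec = spec, seed = seed)
}

synth_metadata <- function(cls, subjects, spec) {
  n <- length(cls); pos <- cls == 2L
  n2 <- sum(pos)
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  age <- integer(n)
  age[pos] <- round(clip(stats::rnorm(n2, 52, 13), 26, 76))
  age[!pos] <- round(clip(stats::rnorm(n - n2, 55.8, 12), 30, 75))

  bmi <- numeric(n)
  if (spec$bmi_association) {
    # all GM-positive above the cut; ~4/9 of GM-negative above it
    bmi[pos] <- round(clip(stats::rnorm(n2, 45, 9), 30.6, 66.3), 1)
    n_hi1 <- round(sum(!pos) * 4 / 9)
    hi1 <- sample(which(!pos), n_hi1)
    bmi[hi1] <- round(clip(stats::rnorm(n_hi1, 40, 7), 30.2, 56.4), 1)
    lo1 <- setdiff(which(!pos), hi1)
    bmi[lo1] <- round(clip(stats::rnorm(length(lo1), 26, 2.5), 21.6, 29.6), 1)
  } else {
    bmi <- round(clip(stats::rnorm(n, 34, 8), 20, 60), 1)
  }

  rank <- integer(n)
  if (spec$enrollment_association && n >= 3L) {
    early_n <- min(8L, n - 1L)
    n2_early <- min(1L, n2)   # one positive among the early block
    early_pos <- sample(which(pos), n2_early)
    early_rest <- sample(which(!pos), min(early_n - n2_early, sum(!pos)))
    early <- c(early_pos, early_rest)
    rank[early] <- sample(seq_len(length(early)))
    late <- setdiff(seq_len(n), early)
    rank[late] <- length(early) + sample(seq_len(length(late)))
  } else {
    rank <- sample(seq_len(n))
  }

  rbern <- function(idx, p) stats::runif(length(idx)) < p
  cancer <- character(n)
  cancer[pos] <- ifelse(rbern(which(pos), 0.5), "cervical", "endometrial")
  cancer[!pos] <- ifelse(rbern(which(!pos), 7 / 9), "cervical", "endometrial")

  data.frame(
    subject_id = subjects,
    gm_grade = ifelse(pos, sample(1:2, n, replace = TRUE), 0L),
    class_label = cls,
    age = age, bmi = bmi, enrollment_rank = rank,
    cancer_type = cancer,
    smoker = ifelse(pos, rbern(seq_len(n), 0.625), rbern(seq_len(n), 0.556)),
    chemoradiation = ifelse(pos, rbern(seq_len(n), 0.5),
                            rbern(seq_len(n), 0.667)),
    brachytherapy = ifelse(pos, rbern(seq_len(n), 0.75),
                           rbern(seq_len(n), 0.667)))
}

#' Generate a cohort with no class signal
#'
#' Same shapes and marginals as [generate_cohort()] but with
#' `effect_scale = 0` and the covariate associations switched off, so the
#' two classes are statistically indistinguishable. Used as the null
#' harness for the permutation control.
#'
#' @inheritParams generate_cohort
#' @export
generate_null_cohort <- function(spec = cohort_spec(), seed = spec$seed) {
  spec$effect_scale <- 0
  spec$bmi_association <- FALSE
  spec$enrollment_association <- FALSE
  generate_cohort(spec, seed)
}

#' Write a synthetic cohort to CSV files
#'
#' Emits `counts.csv` (long format, the dialect [average_replicates()]
#' consumes) and `meta.csv` into `dir`, with the generator seed recorded
#' in a comment header line.
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisible character vector of the two paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("counts.csv", "meta.csv"))
  for (k in 1:2) {
    con <- file(paths[k], "w")
    writeLines(paste0("# synthetic cohort; seed=", cohort$seed), con)
    utils::write.csv(cohort[[c("counts", "meta")[k]]], con, row.names = FALSE)
    close(con)
  }
  invisible(paths)
}

#' Read a long-format raw count table from CSV
#'
#' @param path CSV with columns `subject_id`, `replicate_id`,
#'   `protein_id`, `gene_id`, `count`; `#` lines are comments.
#' @return data frame suitable for [average_replicates()].
#' @export
read_raw_counts <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a subject metadata table from CSV
#'
#' @param path CSV with the subject metadata fields; `#` lines are
#'   comments.
#' @return data frame.
#' @export
read_metadata <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
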