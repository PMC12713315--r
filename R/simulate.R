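#' Simulation configuration for genotype matrices
#'
#' Defaults emulate a small homogeneous discovery cohort: 96 samples,
#' independent common SNPs at Hardy-Weinberg equilibrium with minor-allele
#' frequencies uniform on \[0.05, 0.5\], no missingness.
#'
#' @param n_samples,n_snps positive counts
#' @param maf_low,maf_high minor-allele frequency bounds, 0 < low <= high <= 0.5
#' @param ld_block_size SNPs per linkage block; 1 = independent SNPs
#' @param ld_rho latent gamete correlation between adjacent SNPs in a block,
#'   in \[0, 1)
#' @param missing_rate per-genotype missing probability in \[0, 1)
#' @param seed integer RNG seed
#' @return a `sim_config` list
#' @export
sim_config <- function(n_samples = 96, n_snps = 1000, maf_low = 0.05,
                       maf_high = 0.5, ld_block_size = 1, ld_rho = 0,
                       missing_rate = 0, seed = 1) {
  if (n_samples < 1 || n_snps < 1) stop("non-positive dimensions", call. = FALSE)
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("need 0 < maf_low <= maf_high <= 0.5", call. = FALSE)
  if (ld_block_size < 1) stop("ld_block_size must be >= 1", call. = FALSE)
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
                 maf_low = maf_low, maf_high = maf_high,
                 ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# AR(1) latent gametes within a block, thresholded at qnorm(maf): each
# gamete's allele is Bernoulli(maf) marginally, gametes are independent,
# so every SNP is at HWE exactly; adjacent SNPs are positively correlated.
sim_gamete_block <- function(n, mafs, rho) {
  b <- length(mafs)
  z <- matrix(stats::rnorm(n * b), n, b)
  if (rho > 0 && b > 1) {
    for (j in 2:b) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
  }
  thr <- stats::qnorm(mafs)
  sweep(z, 2, thr, `<`) * 1L
}

#' Simulate a genotype matrix at Hardy-Weinberg equilibrium
#'
#' Per-SNP minor-allele frequencies are drawn uniformly on
#' \[`maf_low`, `maf_high`\].  Genotypes are the sum of two independent
#' latent-Gaussian gametes (a Gaussian-copula block scheme), so each SNP is
#' at HWE marginally while SNPs inside an LD block are positively
#' correlated.  Missing entries are masked completely at random.
#'
#' @param config a [sim_config()]
#' @return a `genotype_matrix`; the variant table carries the true simulated
#'   frequency in a `true_maf` column
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples; m <- config$n_snps
  mafs <- stats::runif(m, config$maf_low, config$maf_high)
  blocks <- split(seq_len(m), ceiling(seq_len(m) / config$ld_block_size))
  geno <- matrix(0L, n, m)
  for (idx in blocks) {
    g1 <- sim_gamete_block(n, mafs[idx], config$ld_rho)
    g2 <- sim_gamete_block(n, mafs[idx], config$ld_rho)
    geno[, idx] <- g1 + g2
  }
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    geno[mask] <- NA_integer_
  }
  bases <- c("A", "C", "G", "T")
  a_idx <- sample.int(4, m, replace = TRUE)
  b_off <- sample.int(3, m, replace = TRUE)
  allele1 <- bases[a_idx]
  allele2 <- bases[(a_idx - 1 + b_off) %% 4 + 1]
  variants <- data.frame(
    chr = rep(1L, m),
    pos = seq_len(m) * 1000L,
    snp_id = sprintf("rs%06d", seq_len(m)),
    allele1 = allele1, allele2 = allele2,
    true_maf = mafs,
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    sex = sample(1:2, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  genotype_matrix(geno, variants, samples)
}

#' Generative model for one binary trait
#'
#' Disease status is Bernoulli(logistic(eta)) with
#' `eta = intercept + sex_beta * (sex == 2) + sum(additive) +
#' sum(interaction) + trait_correlation * Z_shared`, where additive terms
#' are log-odds per minor-allele copy, interaction terms log-odds per
#' product of copy counts, and `Z_shared` is a standard-normal liability
#' shared by all traits of one cohort.
#'
#' @param intercept baseline log-odds
#' @param sex_beta log-odds for female (sex == 2) vs male
#' @param additive_effects named numeric vector: SNP id or index -> log-odds
#'   per allele copy
#' @param interaction_effects optional data frame with columns `snp1`,
#'   `snp2`, `beta` (log-odds per product of copy counts); `snp1 != snp2`
#' @param trait_correlation coefficient on the shared liability, in \[0, 1)
#' @return a `trait_model` list
#' @export
trait_model <- function(intercept = 0, sex_beta = 0, additive_effects = numeric(0),
                        interaction_effects = NULL, trait_correlation = 0) {
  if (trait_correlation < 0 || trait_correlation >= 1)
    stop("trait_correlation must be in [0, 1)", call. = FALSE)
  if (!is.null(interaction_effects)) {
    stopifnot(is.data.frame(interaction_effects),
              all(c("snp1", "snp2", "beta") %in% names(interaction_effects)))
    if (any(interaction_effects$snp1 == interaction_effects$snp2))
      stop("interaction pairs (i, i) are not allowed", call. = FALSE)
  }
  structure(list(intercept = intercept, sex_beta = sex_beta,
                 additive_effects = additive_effects,
                 interaction_effects = interaction_effects,
                 trait_correlation = trait_correlation),
            class = "trait_model")
}

resolve_snp_ref <- function(ref, G) {
  if (is.numeric(ref)) {
    idx <- as.integer(ref)
    if (any(idx < 1 | idx > ncol(G$geno)))
      stop("SNP index out of range", call. = FALSE)
    return(idx)
  }
  idx <- match(as.character(ref), G$variants$snp_id)
  if (anyNA(idx)) stop("unknown SNP id: ", paste(ref[is.na(idx)], collapse = ", "),
                       call. = FALSE)
  idx
}

#' Simulate correlated binary traits from a genotype matrix
#'
#' @param G a `genotype_matrix`; missing genotypes enter the linear
#'   predictor at the per-SNP mean dosage
#' @param models named list of [trait_model()]s, one per trait
#' @param seed integer RNG seed
#' @return list with `samples` (the sample table of `G` extended by one
#'   PLINK-coded status column per trait) and `ground_truth` (causal SNP
#'   ids, interaction pairs, realized per-trait prevalence)
#' @export
simulate_phenotypes <- function(G, models, seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"), is.list(models), length(models) >= 1)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    stop("`models` must be a named list (one name per trait)", call. = FALSE)
  set.seed(as.integer(seed))
  n <- nrow(G$geno)
  sex <- G$samples$sex
  if (is.null(sex)) sex <- sample(1:2, n, replace = TRUE)
  dose <- G$geno
  if (anyNA(dose)) {
    mu <- colMeans(dose, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    for (j in which(colSums(is.na(dose)) > 0))
      dose[is.na(dose[, j]), j] <- mu[j]
  }
  z_shared <- stats::rnorm(n)
  samples <- G$samples
  causal <- character(0)
  pairs <- list()
  prevalence <- numeric(0)
  for (trait in names(models)) {
    mod <- models[[trait]]
    stopifnot(inherits(mod, "trait_model"))
    eta <- rep(mod$intercept, n) + mod$sex_beta * (sex == 2)
    if (length(mod$additive_effects)) {
      refs <- if (is.null(names(mod$additive_effects)) ||
                  any(!nzchar(names(mod$additive_effects))))
        seq_along(mod$additive_effects) else names(mod$additive_effects)
      idx <- resolve_snp_ref(refs, G)
      eta <- eta + as.vector(dose[, idx, drop = FALSE] %*% unname(mod$additive_effects))
      causal <- union(causal, G$variants$snp_id[idx])
    }
    if (!is.null(mod$interaction_effects)) {
      for (r in seq_len(nrow(mod$interaction_effects))) {
        i <- resolve_snp_ref(mod$interaction_effects$snp1[r], G)
        j <- resolve_snp_ref(mod$interaction_effects$snp2[r], G)
        eta <- eta + mod$interaction_effects$beta[r] * dose[, i] * dose[, j]
        pairs[[length(pairs) + 1]] <- sort(G$variants$snp_id[c(i, j)])
      }
    }
    eta <- eta + mod$trait_correlation * z_shared
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    samples[[trait]] <- ifelse(y == 1, 2L, 1L)
    prevalence[trait] <- mean(y)
  }
  list(samples = samples,
       ground_truth = list(causal_snp_ids = causal,
                           interaction_pairs = unique(pairs),
                           prevalence = prevalence))
}

#' Solve the intercept giving a target prevalence
#'
#' Tunes the trait-model intercept so the expected case fraction under the
#' model (averaged over the cohort's genotypes and sexes) equals `target`.
#'
#' @param model a [trait_model()] (its intercept is ignored)
#' @param G a `genotype_matrix`
#' @param target target prevalence in (0, 1)
#' @return the intercept (log-odds)
#' @export
intercept_for_prevalence <- function(model, G, target) {
  stopifnot(target > 0, target < 1)
  n <- nrow(G$geno)
  sex <- G$samples$sex
  dose <- G$geno
  if (anyNA(dose)) {
    mu <- colMeans(dose, na.rm = TRUE); mu[is.nan(mu)] <- 0
    for (j in which(colSums(is.na(dose)) > 0)) dose[is.na(dose[, j]), j] <- mu[j]
  }
  eta0 <- rep(0, n) + model$sex_beta * (sex == 2)
  if (length(model$additive_effects)) {
    refs <- if (is.null(names(model$additive_effects)) ||
                any(!nzchar(names(model$additive_effects))))
      seq_along(model$additive_effects) else names(model$additive_effects)
    idx <- resolve_snp_ref(refs, G)
    eta0 <- eta0 + as.vector(dose[, idx, drop = FALSE] %*% unname(model$additive_effects))
  }
  if (!is.null(model$interaction_effects)) {
    for (r in seq_len(nrow(model$interaction_effects))) {
      i <- resolve_snp_ref(model$interaction_effects$snp1[r], G)
      j <- resolve_snp_ref(model$interaction_effects$snp2[r], G)
      eta0 <- eta0 + model$interaction_effects$beta[r] * dose[, i] * dose[, j]
    }
  }
  stats::uniroot(function(a) mean(stats::plogis(a + eta0)) - target,
                 lower = -25, upper = 25)$root
}

#' Resample a simulated cohort to exact case/control counts
#'
#' Draws without replacement `n_case` cases and `n_control` controls for one
#' trait, emulating a designed cohort (e.g. 80 cases / 16 controls) from a
#' population-prevalence simulation.
#'
#' @param G a `genotype_matrix` whose sample table carries `trait`
#' @param trait trait column name
#' @param n_case,n_control counts to draw
#' @param seed integer RNG seed
#' @return a `genotype_matrix` with exactly the requested counts
#' @export
resample_to_counts <- function(G, trait, n_case, n_control, seed = 1) {
  y <- trait_status(G, trait)
  cases <- which(y == 1L); controls <- which(y == 0L)
  if (length(cases) < n_case || length(controls) < n_control)
    stop("not enough cases/controls to resample (have ", length(cases), "/",
         length(controls), ")", call. = FALSE)
  set.seed(as.integer(seed))
  keep <- sort(c(sample(cases, n_case), sample(controls, n_control)))
  subset_genotypes(G, samples = keep)
}

#' Visit-record simulation configuration
#'
#' @param n_patients number of patients (0 allowed: empty table)
#' @param code_prevalences named numeric vector, ICD code -> marginal
#'   prevalence in (0, 1)
#' @param planted_pairs optional data frame with columns `antecedent`,
#'   `consequent`, `lift` (target lift >= 0); the implied conditional
#'   P(C|D) = lift * P(C) must be <= 1, and the complementary conditional
#'   P(C|not D) must be a probability
#' @param seed integer RNG seed
#' @return a `visit_sim_config` list
#' @export
visit_sim_config <- function(n_patients, code_prevalences, planted_pairs = NULL,
                             seed = 1) {
  if (n_patients < 0) stop("n_patients must be >= 0", call. = FALSE)
  if (is.null(names(code_prevalences)) || any(!nzchar(names(code_prevalences))))
    stop("code_prevalences must be named by ICD code", call. = FALSE)
  if (any(code_prevalences <= 0 | code_prevalences >= 1))
    stop("code prevalences must be in (0, 1)", call. = FALSE)
  if (!is.null(planted_pairs)) {
    stopifnot(is.data.frame(planted_pairs),
              all(c("antecedent", "consequent", "lift") %in% names(planted_pairs)))
    for (r in seq_len(nrow(planted_pairs))) {
      d <- planted_pairs$antecedent[r]; cc <- planted_pairs$consequent[r]
      lift <- planted_pairs$lift[r]
      if (!d %in% names(code_prevalences) || !cc %in% names(code_prevalences))
        stop("planted pair references unknown code", call. = FALSE)
      pD <- code_prevalences[[d]]; pC <- code_prevalences[[cc]]
      if (lift < 0) stop("lift must be >= 0", call. = FALSE)
      if (lift * pC > 1)
        stop("invalid planted pair: lift * P(C) = ", lift * pC, " > 1", call. = FALSE)
      pC_notD <- pC * (1 - lift * pD) / (1 - pD)
      if (pC_notD < 0 || pC_notD > 1)
        stop("invalid planted pair: implied P(C | not D) = ",
             signif(pC_notD, 4), " outside [0, 1]", call. = FALSE)
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 code_prevalences = code_prevalences,
                 planted_pairs = planted_pairs, seed = as.integer(seed)),
            class = "visit_sim_config")
}

#' Simulate visit records with planted comorbidity lift
#'
#' Each patient receives each code independently at its marginal prevalence,
#' except planted consequents, which are drawn conditionally on the
#' antecedent so that lift(D -> C) equals the target while the marginal
#' prevalence of C is preserved.
#'
#' @param config a [visit_sim_config()]
#' @return data frame (`patient_id`, `icd9_code`) of positive diagnoses,
#'   with attribute `n_patients`
#' @export
simulate_visits <- function(config) {
  stopifnot(inherits(config, "visit_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  codes <- names(config$code_prevalences)
  if (n == 0) {
    out <- data.frame(patient_id = character(0), icd9_code = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_patients") <- 0L
    return(out)
  }
  planted_consequents <- if (is.null(config$planted_pairs)) character(0) else
    unique(config$planted_pairs$consequent)
  has <- matrix(FALSE, n, length(codes), dimnames = list(NULL, codes))
  for (code in setdiff(codes, planted_consequents))
    has[, code] <- stats::runif(n) < config$code_prevalences[[code]]
  if (length(planted_consequents)) {
    for (r in seq_len(nrow(config$planted_pairs))) {
      d <- config$planted_pairs$antecedent[r]
      cc <- config$planted_pairs$consequent[r]
      lift <- config$planted_pairs$lift[r]
      pD <- config$code_prevalences[[d]]; pC <- config$code_prevalences[[cc]]
      pC_D <- lift * pC
      pC_notD <- pC * (1 - lift * pD) / (1 - pD)
      p <- ifelse(has[, d], pC_D, pC_notD)
      has[, cc] <- stats::runif(n) < p
    }
  }
  idx <- which(has, arr.ind = TRUE)
  out <- data.frame(patient_id = sprintf("P%05d", idx[, 1]),
                    icd9_code = codes[idx[, 2]], stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$icd9_code), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_patients") <- n
  out
}
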