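# Synthetic 450k-style cohorts with the statistical structure the classifier
# assumes: subtype-specific hypomethylation signatures (BCP subtypes low at
# beta ~0.19 against a ~0.85 background; T-ALL inverted at 0.92 vs 0.04), a
# normal-blood reference signature, sex-differential chrX sites, partial
# HeH/iAMP21 signature sharing, and intensity-level aneuploidy signal scaled
# by blast fraction. Beta noise is a Beta distribution reparameterized by
# median and concentration, so values respect [0,1] without clipping.

default_cna_events <- function() {
  rbind(
    data.frame(subtype = "HeH",
               chromosome = paste0("chr", c(4, 6, 10, 14, 17, 18, 21, "X")),
               arm = "both", copy_number = 3, stringsAsFactors = FALSE),
    data.frame(subtype = "iAMP21", chromosome = "chr21", arm = "q",
               copy_number = 4, stringsAsFactors = FALSE),
    data.frame(subtype = "dic(9;20)",
               chromosome = c("chr9", "chr20"), arm = c("p", "q"),
               copy_number = 1, stringsAsFactors = FALSE))
}

#' Generator configuration for synthetic cohorts
#'
#' Defaults mirror the design cohort the classifier targets: the eight
#' subtype sample counts (101/189/161/27/21/20/19/8, total 546) plus 139
#' non-leukemic reference samples, 30 planted signature CpGs per task at
#' median beta 0.19 in the own subtype against a 0.85 background (T-ALL
#' inverted: 0.92 own vs 0.04 in the BCP subtypes), 76% of the HeH
#' signature shared by iAMP21 samples, and arm/chromosome copy-number
#' events per subtype (high-hyperdiploid trisomies, the iAMP21 21q
#' amplification, dic(9;20) 9p/20q losses) diluted by a per-sample blast
#' fraction.
#'
#' @param n_probes number of probes (default 5000; the full 450k scale is
#'   supported at proportional cost).
#' @param n_signature_sites signature CpGs planted per task (default 30).
#' @param subtype_sample_counts named integer vector over
#'   [mall_subtypes()].
#' @param n_reference number of non-leukemic reference samples.
#' @param signature_beta_own,background_beta BCP signature medians (own
#'   subtype / everyone else).
#' @param tall_signature_beta_own,tall_background T-ALL signature medians.
#' @param reference_signature_beta reference-signature median in reference
#'   samples (background elsewhere).
#' @param sex_beta_f,sex_beta_m chrX sex-site medians for females / males.
#' @param beta_noise_concentration Beta-distribution concentration (higher
#'   = tighter around the median; `Inf` = noise-free). Default 10, i.e. a
#'   per-site beta SD near 0.1.
#' @param sex_site_count number of chrX sex sites (default 30).
#' @param missing_rate fraction of beta cells masked missing.
#' @param blast_fraction_range range of the per-sample leukemic blast
#'   fraction diluting the copy-number signal.
#' @param heh_shared_fraction fraction of HeH signature sites also
#'   hypomethylated in iAMP21 samples (default 0.76).
#' @param cna_events data.frame (`subtype`, `chromosome`, `arm` of
#'   `p`/`q`/`both`, `copy_number`) of planted events.
#' @param intensity_base_meanlog,intensity_base_sdlog lognormal parameters
#'   of the per-probe baseline total intensity.
#' @param intensity_noise_sdlog multiplicative intensity noise (lognormal
#'   sdlog).
#' @param sample_scale_range per-sample global intensity scale factor range
#'   (removed by quantile normalization).
#' @param seed integer seed.
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(n_probes = 5000,
                             n_signature_sites = 30,
                             subtype_sample_counts = c(
                               "T-ALL" = 101, "HeH" = 189, "t(12;21)" = 161,
                               "11q23/MLL" = 27, "t(1;19)" = 21,
                               "dic(9;20)" = 20, "t(9;22)" = 19,
                               "iAMP21" = 8),
                             n_reference = 139,
                             signature_beta_own = 0.19,
                             background_beta = 0.85,
                             tall_signature_beta_own = 0.92,
                             tall_background = 0.04,
                             reference_signature_beta = 0.19,
                             sex_beta_f = 0.55,
                             sex_beta_m = 0.12,
                             beta_noise_concentration = 10,
                             sex_site_count = 30,
                             missing_rate = 0.002,
                             blast_fraction_range = c(0.6, 1),
                             heh_shared_fraction = 0.76,
                             cna_events = default_cna_events(),
                             intensity_base_meanlog = log(3000),
                             intensity_base_sdlog = 1.0,
                             intensity_noise_sdlog = 0.1,
                             sample_scale_range = c(0.85, 1.15),
                             seed = 1) {
  cfg <- list(n_probes = as.integer(n_probes),
              n_signature_sites = as.integer(n_signature_sites),
              subtype_sample_counts = subtype_sample_counts,
              n_reference = as.integer(n_reference),
              signature_beta_own = signature_beta_own,
              background_beta = background_beta,
              tall_signature_beta_own = tall_signature_beta_own,
              tall_background = tall_background,
              reference_signature_beta = reference_signature_beta,
              sex_beta_f = sex_beta_f, sex_beta_m = sex_beta_m,
              beta_noise_concentration = beta_noise_concentration,
              sex_site_count = as.integer(sex_site_count),
              missing_rate = missing_rate,
              blast_fraction_range = blast_fraction_range,
              heh_shared_fraction = heh_shared_fraction,
              cna_events = cna_events,
              intensity_base_meanlog = intensity_base_meanlog,
              intensity_base_sdlog = intensity_base_sdlog,
              intensity_noise_sdlog = intensity_noise_sdlog,
              sample_scale_range = sample_scale_range,
              seed = as.integer(seed))
  meds <- c(cfg$signature_beta_own, cfg$background_beta,
            cfg$tall_signature_beta_own, cfg$tall_background,
            cfg$reference_signature_beta, cfg$sex_beta_f, cfg$sex_beta_m)
  if (any(meds < 0 | meds > 1))
    mall_config_error("all target medians must lie in [0,1]")
  if (!setequal(names(cfg$subtype_sample_counts), mall_subtypes()))
    mall_config_error("subtype_sample_counts must name all eight subtypes")
  if (any(cfg$subtype_sample_counts < 0) || cfg$n_reference < 0)
    mall_config_error("sample counts must be >= 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    mall_config_error("missing_rate must lie in [0,1)")
  n_needed <- cfg$n_signature_sites * (length(mall_subtypes()) + 1)
  if (n_needed > cfg$n_probes)
    mall_config_error(sprintf(
      "signature sites x tasks (%d) exceed n_probes (%d)", n_needed,
      cfg$n_probes))
  structure(cfg, class = "generator_config")
}

# Shape parameters of a Beta(mu*nu, (1-mu)*nu) whose *median* equals m,
# solved once per distinct target and interpolated on a monotone spline.
beta_shapes_for_median <- function(m, nu) {
  solve_one <- function(target) {
    # qbeta warns (harmlessly) at the extreme shapes probed by uniroot's
    # bracket endpoints; the root itself lies well inside.
    f <- function(mu) suppressWarnings(
      stats::qbeta(0.5, mu * nu, (1 - mu) * nu)) - target
    stats::uniroot(f, c(1e-6, 1 - 1e-6), tol = 1e-12)$root
  }
  grid_m <- seq(0.005, 0.995, length.out = 199)
  mu_grid <- vapply(grid_m, solve_one, numeric(1))
  fn <- stats::splinefun(grid_m, mu_grid, method = "monoH.FC")
  mu <- pmin(pmax(fn(pmin(pmax(m, 0.005), 0.995)), 1e-8), 1 - 1e-8)
  list(shape1 = mu * nu, shape2 = (1 - mu) * nu)
}

draw_betas <- function(target_median, nu) {
  if (!is.finite(nu)) return(target_median)
  sh <- beta_shapes_for_median(as.vector(target_median), nu)
  out <- stats::rbeta(length(target_median), sh$shape1, sh$shape2)
  dim(out) <- dim(target_median)
  dimnames(out) <- dimnames(target_median)
  out
}

#' Simulate a 450k-style cohort
#'
#' Draws probe annotations (uniform chromosome assignment, positions
#' uniform along hg19 chromosome lengths), a sample sheet per the
#' configured subtype counts, beta values around per-site target medians
#' (see [generator_config()]), and paired methylated/unmethylated
#' intensity matrices carrying the planted copy-number signal: on probes of
#' an aberrant region the total intensity is multiplied by
#' `(f*c + (1-f)*2) / 2` for copy number `c` at blast fraction `f`. Fully
#' reproducible from `config$seed`.
#'
#' @param config a `generator_config`.
#' @return list with `data` (a `methyl_matrix` with missing cells masked),
#'   `meth`/`unmeth` (`intensity_matrix` pair), and `truth`: per-sample
#'   subtype/sex/class/blast fraction, per-task planted signature site ids,
#'   the HeH sites shared with iAMP21, and the planted CNA events.
#' @export
simulate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    arms <- hg19_arms()
    chr_len <- vapply(mall_chromosomes(), function(ch)
      max(arms$end[arms$chromosome == ch]), numeric(1))
    p <- config$n_probes
    chrom <- sample(mall_chromosomes(), p, replace = TRUE)
    pos <- as.integer(floor(stats::runif(p, 1, chr_len[chrom] + 1)))
    ord <- order(match(chrom, mall_chromosomes()), pos)
    probes <- data.frame(
      probe_id = sprintf("cg%07d", seq_len(p)),
      chromosome = chrom[ord], position = pos[ord],
      gene = ifelse(stats::runif(p) < 0.95,
                    sprintf("GENE%04d", sample.int(2000, p, replace = TRUE)),
                    NA_character_),
      cgi_relation = sample(cgi_levels(), p, replace = TRUE,
                            prob = c(0.13, 0.23, 0.1, 0.54)),
      stringsAsFactors = FALSE)

    subs <- mall_subtypes()
    counts <- config$subtype_sample_counts[subs]
    subtype_of <- rep(subs, counts)
    n_all <- length(subtype_of)
    n_ref <- config$n_reference
    samples <- data.frame(
      sample_id = c(sprintf("ALL_%04d", seq_len(n_all)),
                    sprintf("REF_%04d", seq_len(n_ref))),
      sample_class = c(rep("ALL", n_all), rep("reference", n_ref)),
      sex = sample(c("M", "F"), n_all + n_ref, replace = TRUE),
      subtype_label = c(subtype_of, rep("unknown", n_ref)),
      stringsAsFactors = FALSE)
    n <- nrow(samples)

    # Disjoint signature sets: autosomal sites for the subtype and
    # reference tasks, chrX sites for the sex task.
    auto_idx <- which(!probes$chromosome %in% c("chrX", "chrY"))
    x_idx <- which(probes$chromosome == "chrX")
    k <- config$n_signature_sites
    tasks_auto <- c(subs, "reference")
    need_auto <- k * length(tasks_auto)
    if (length(auto_idx) < need_auto)
      mall_config_error("not enough autosomal probes for the signatures")
    if (length(x_idx) < config$sex_site_count)
      mall_config_error("not enough chrX probes for the sex signature")
    picked <- sample(auto_idx, need_auto)
    sig_sites <- stats::setNames(
      split(picked, rep(tasks_auto, each = k)), tasks_auto)[tasks_auto]
    sex_sites <- sample(x_idx, config$sex_site_count)
    n_shared <- round(config$heh_shared_fraction * k)
    heh_shared <- sig_sites[["HeH"]][seq_len(n_shared)]

    # Target-median matrix: per-probe baseline (bimodal, constant across
    # samples) overwritten on signature sites.
    base_m <- ifelse(stats::runif(p) < 0.4, stats::runif(p, 0.05, 0.25),
                     ifelse(stats::runif(p) < 0.5,
                            stats::runif(p, 0.75, 0.95),
                            stats::runif(p, 0.30, 0.70)))
    target <- matrix(base_m, p, n)
    is_ref <- samples$sample_class == "reference"
    for (st in subs) {
      own <- samples$subtype_label == st
      if (st == "T-ALL") {
        target[sig_sites[[st]], own] <- config$tall_signature_beta_own
        target[sig_sites[[st]], !own] <- config$tall_background
      } else {
        target[sig_sites[[st]], ] <- config$background_beta
        target[sig_sites[[st]], own] <- config$signature_beta_own
      }
    }
    is_iamp <- samples$subtype_label == "iAMP21"
    target[heh_shared, is_iamp] <- config$signature_beta_own
    target[sig_sites[["reference"]], ] <- config$background_beta
    target[sig_sites[["reference"]], is_ref] <- config$reference_signature_beta
    target[sex_sites, ] <- ifelse(
      matrix(samples$sex == "F", p, n, byrow = TRUE)[sex_sites, ],
      config$sex_beta_f, config$sex_beta_m)

    beta <- draw_betas(target, config$beta_noise_concentration)
    beta_complete <- beta
    if (config$missing_rate > 0) {
      mask <- stats::runif(length(beta)) < config$missing_rate
      beta[mask] <- NA_real_
    }
    dimnames(beta) <- list(probes$probe_id, samples$sample_id)

    # Copy-number factor per (probe, sample) from the planted events.
    blast <- stats::runif(n, config$blast_fraction_range[1],
                          config$blast_fraction_range[2])
    blast[is_ref] <- NA_real_
    cn_factor <- matrix(1, p, n)
    ev <- config$cna_events
    truth_events <- list()
    if (!is.null(ev) && nrow(ev)) {
      for (i in seq_len(nrow(ev))) {
        samp <- which(samples$subtype_label == ev$subtype[i])
        if (!length(samp)) next
        sel_arms <- if (ev$arm[i] == "both") c("p", "q") else ev$arm[i]
        pidx <- integer(0)
        for (a in sel_arms) {
          b <- arms[arms$chromosome == ev$chromosome[i] & arms$arm == a, ]
          pidx <- c(pidx, which(probes$chromosome == ev$chromosome[i] &
                                  probes$position >= b$start &
                                  probes$position <= b$end))
        }
        for (j in samp) {
          f <- blast[j]
          cn_factor[pidx, j] <- (f * ev$copy_number[i] + (1 - f) * 2) / 2
        }
        truth_events[[length(truth_events) + 1]] <- data.frame(
          sample_id = samples$sample_id[samp],
          chromosome = ev$chromosome[i], arm = ev$arm[i],
          copy_number = ev$copy_number[i], blast_fraction = blast[samp],
          stringsAsFactors = FALSE)
      }
    }
    truth_cna <- if (length(truth_events)) do.call(rbind, truth_events)
    else data.frame(sample_id = character(0), chromosome = character(0),
                    arm = character(0), copy_number = numeric(0),
                    blast_fraction = numeric(0))

    base_int <- stats::rlnorm(p, config$intensity_base_meanlog,
                              config$intensity_base_sdlog)
    scale_s <- stats::runif(n, config$sample_scale_range[1],
                            config$sample_scale_range[2])
    noise <- if (config$intensity_noise_sdlog > 0)
      matrix(stats::rlnorm(p * n, 0, config$intensity_noise_sdlog), p, n)
    else 1
    total <- base_int * cn_factor * noise
    total <- sweep(total, 2, scale_s, "*")
    meth_v <- total * beta_complete
    unmeth_v <- total - meth_v

    truth <- list(
      samples = data.frame(sample_id = samples$sample_id,
                           sample_class = samples$sample_class,
                           subtype = samples$subtype_label,
                           sex = samples$sex, blast_fraction = blast,
                           stringsAsFactors = FALSE),
      signature_sites = c(
        lapply(sig_sites, function(ix) probes$probe_id[ix]),
        list(sex = probes$probe_id[sex_sites])),
      heh_shared_sites = probes$probe_id[heh_shared],
      cna_events = truth_cna)

    list(data = methyl_matrix(beta, probes, samples),
         meth = intensity_matrix(meth_v, probes, samples, "methylated"),
         unmeth = intensity_matrix(unmeth_v, probes, samples, "unmethylated"),
         truth = truth)
  })
}

#' Recovery metrics against generator truth
#'
#' Deterministic scorecard of a pipeline run on a simulated cohort:
#' per-task consensus-site recovery (precision/recall against the planted
#' signatures), subtype call accuracy over leukemic samples, and planted
#' CNA event recovery.
#'
#' @param truth the `truth` element of [simulate_cohort()].
#' @param outcomes optional `cohort_calls` (or its `$outcomes`) on the same
#'   samples.
#' @param classifier optional trained `subtype_classifier`.
#' @param arm_events optional `events` table from [call_arm_events()].
#' @return list with any of `site_recovery` (per task: n_planted,
#'   n_consensus, recall, precision), `call_accuracy` (fraction of ALL
#'   samples called single-class with the true label), and `cna_recovery`
#'   (fraction of planted arm events called with the right direction).
#' @export
truth_report <- function(truth, outcomes = NULL, classifier = NULL,
                         arm_events = NULL) {
  out <- list()
  if (!is.null(classifier)) {
    stopifnot(inherits(classifier, "subtype_classifier"))
    rec <- lapply(names(truth$signature_sites), function(tid) {
      planted <- truth$signature_sites[[tid]]
      got <- if (!is.null(classifier$tasks[[tid]]))
        classifier$tasks[[tid]]$consensus$consensus_sites else character(0)
      data.frame(task = tid, n_planted = length(planted),
                 n_consensus = length(got),
                 recall = if (length(planted))
                   length(intersect(got, planted)) / length(planted)
                 else NA_real_,
                 precision = if (length(got))
                   length(intersect(got, planted)) / length(got)
                 else NA_real_,
                 n_false = length(setdiff(got, planted)),
                 stringsAsFactors = FALSE)
    })
    out$site_recovery <- do.call(rbind, rec)
  }
  if (!is.null(outcomes)) {
    if (inherits(outcomes, "cohort_calls")) outcomes <- outcomes$outcomes
    tr <- truth$samples
    m <- match(outcomes$sample_id, tr$sample_id)
    if (anyNA(m))
      mall_value_error("outcome sample ids do not match the truth set")
    is_all <- tr$sample_class[m] == "ALL"
    correct <- outcomes$category == "single_class" &
      outcomes$assigned_subtype == tr$subtype[m]
    out$call_accuracy <- if (any(is_all)) mean(correct[is_all]) else NA_real_
  }
  if (!is.null(arm_events)) {
    ev <- truth$cna_events
    if (nrow(ev)) {
      hits <- logical(0)
      for (i in seq_len(nrow(ev))) {
        sel_arms <- if (ev$arm[i] == "both") c("p", "q") else ev$arm[i]
        want <- if (ev$copy_number[i] > 2) "gain" else "loss"
        for (a in sel_arms) {
          an <- paste0(sub("^chr", "", ev$chromosome[i]), a)
          row <- arm_events[arm_events$sample_id == ev$sample_id[i] &
                              arm_events$arm == an, ]
          if (nrow(row)) hits <- c(hits, row$call[1] == want)
        }
      }
      out$cna_recovery <- mean(hits)
    } else out$cna_recovery <- NA_real_
  }
  out
}
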