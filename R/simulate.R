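#' Configuration of the synthetic AP-MS experiment
#'
#' Describes a simulated TMT-multiplexed AP-MS pull-down in the 3 + 3 + 3
#' design (3 wild-type bait, 3 variant bait, 3 no-transfection control
#' channels) with four protein classes:
#'
#' * `BAIT`: the bait itself, tracking the per-channel bait level.
#' * `BACKGROUND_BINDER`: bait-dependent preys with equal affinity for both
#'   bait variants (true fold 1); in control channels only a carryover
#'   fraction `control_carryover` of their binding signal remains.
#' * `NONSPECIFIC`: bead/tube binders with equal expected signal in every
#'   channel, control or experimental -- the class the negative-control
#'   filter must remove.
#' * `DIFFERENTIAL`: bait-dependent preys enriched on the variant bait by
#'   the planted fold `differential_fold`.
#'
#' All abundances carry multiplicative log-normal noise with coefficient
#' of variation `noise_cv`, so a log2-scale t-test is exactly calibrated.
#' Per-channel bait levels get a uniform `+/- bait_level_jitter` relative
#' jitter, which bait normalization must cancel.
#'
#' @param n_background_binders Number of non-differential bait-dependent
#'   preys (default 200).
#' @param n_nonspecific Number of nonspecific binders (default 100).
#' @param n_differential Number of differentially enriched preys
#'   (default 20).
#' @param differential_fold Planted variant/WT fold for `DIFFERENTIAL`
#'   preys (default 2).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal noise (default 0.10).
#' @param bait_level Mean bait abundance per experimental channel
#'   (default 1000).
#' @param bait_level_jitter Relative half-width of the uniform per-channel
#'   bait-level jitter (default 0.10).
#' @param control_carryover Fraction of a bait-dependent prey's binding
#'   signal remaining in no-transfection control channels, in (0, 1]
#'   (default 0.3).
#' @param binding_meanlog,binding_sdlog Log-normal parameters of the
#'   per-prey binding scale (defaults `log(50)` and 1).
#' @param seed Optional RNG seed making [simulate_apms()] deterministic.
#' @return An `apms_sim_config` list.
#' @export
apms_sim_config <- function(n_background_binders = 200L,
                            n_nonspecific = 100L,
                            n_differential = 20L,
                            differential_fold = 2,
                            noise_cv = 0.10,
                            bait_level = 1000,
                            bait_level_jitter = 0.10,
                            control_carryover = 0.3,
                            binding_meanlog = log(50),
                            binding_sdlog = 1,
                            seed = NULL) {
  cfg <- list(n_background_binders = as.integer(n_background_binders),
              n_nonspecific = as.integer(n_nonspecific),
              n_differential = as.integer(n_differential),
              differential_fold = differential_fold,
              noise_cv = noise_cv,
              bait_level = bait_level,
              bait_level_jitter = bait_level_jitter,
              control_carryover = control_carryover,
              binding_meanlog = binding_meanlog,
              binding_sdlog = binding_sdlog,
              seed = seed)
  .assert(all(vapply(cfg[1:3], function(x) x >= 0L, logical(1L))),
          "apms_validation_error", "protein counts must be >= 0")
  .assert(cfg$differential_fold > 0, "apms_validation_error",
          "differential_fold must be > 0")
  .assert(cfg$noise_cv > 0, "apms_validation_error", "noise_cv must be > 0")
  .assert(cfg$bait_level > 0 && cfg$bait_level_jitter >= 0 &&
            cfg$bait_level_jitter < 1,
          "apms_validation_error", "bait_level must be > 0 with jitter in [0, 1)")
  .assert(cfg$control_carryover > 0 && cfg$control_carryover <= 1,
          "apms_validation_error", "control_carryover must lie in (0, 1]")
  structure(cfg, class = "apms_sim_config")
}

# log-normal noise factors with unit mean and the requested CV
.lnoise <- function(n, cv) {
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Simulate a TMT AP-MS abundance matrix with ground truth
#'
#' Draws one complete synthetic experiment per the generative model of
#' [apms_sim_config()]: a 3 + 3 + 3 plex layout, a raw abundance matrix
#' (bait plus the three prey classes), and a truth table labelling every
#' protein with its class and planted fold.  For bait-dependent preys the
#' expected experimental abundance in channel `c` is
#' `bait_level_c * binding_i * fold_i^(c is variant)`, and the expected
#' control abundance is `control_carryover * binding_i`; nonspecific preys
#' have expectation `binding_i` in every channel; the bait row carries
#' `bait_level_c` in experimental channels and a carryover-level signal in
#' controls.  Every cell is multiplied by independent log-normal noise.
#' Output is deterministic given `config$seed`.
#'
#' @param config An [apms_sim_config()].
#' @return List with elements `abundance` (an [abundance_matrix()]),
#'   `layout` (a [plex_layout()]) and `truth` (data frame `protein`,
#'   `class`, `true_fold`).
#' @export
simulate_apms <- function(config = apms_sim_config()) {
  stopifnot(inherits(config, "apms_sim_config"))
  .with_seed(config$seed, {
    layout <- plex_layout(
      channels   = c(paste0("WT_", 1:3), paste0("VAR_", 1:3), paste0("CTRL_", 1:3)),
      roles      = rep(c("WT_BAIT", "VARIANT_BAIT", "NEGATIVE_CONTROL"), each = 3L),
      replicates = rep(1:3, times = 3L)
    )
    expch <- experimental_channels(layout)
    ctrl <- control_channels(layout)
    is_var <- expch %in% channels_for_role(layout, "VARIANT_BAIT")

    nbg <- config$n_background_binders
    nns <- config$n_nonspecific
    ndi <- config$n_differential
    cls <- c("BAIT",
             rep("BACKGROUND_BINDER", nbg),
             rep("NONSPECIFIC", nns),
             rep("DIFFERENTIAL", ndi))
    ids <- c("BAIT",
             sprintf("BG_%03d", seq_len(nbg)),
             sprintf("NS_%03d", seq_len(nns)),
             sprintf("DIF_%03d", seq_len(ndi)))
    n <- length(ids)
    fold <- ifelse(cls == "DIFFERENTIAL", config$differential_fold, 1)

    binding <- stats::rlnorm(n, config$binding_meanlog, config$binding_sdlog)
    bait_level_c <- config$bait_level *
      stats::runif(length(expch), 1 - config$bait_level_jitter,
                   1 + config$bait_level_jitter)

    expected <- matrix(0, n, length(expch) + length(ctrl),
                       dimnames = list(ids, c(expch, ctrl)))
    dep <- cls %in% c("BACKGROUND_BINDER", "DIFFERENTIAL")
    fold_ch <- outer(fold[dep], ifelse(is_var, 1, 0), `^`)
    expected[dep, expch] <- (binding[dep] * fold_ch) *
      rep(bait_level_c, each = sum(dep))
    expected[dep, ctrl] <- config$control_carryover * binding[dep]
    ns <- cls == "NONSPECIFIC"
    expected[ns, ] <- binding[ns]
    expected["BAIT", expch] <- bait_level_c
    expected["BAIT", ctrl] <- config$control_carryover * config$bait_level

    values <- expected * .lnoise(length(expected), config$noise_cv)
    values <- values[, layout$channel, drop = FALSE]

    list(abundance = abundance_matrix(values, bait_id = "BAIT"),
         layout = layout,
         truth = data.frame(protein = ids, class = cls, true_fold = fold,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate blinded multi-rater cell counts
#'
#' Emulates the blinded retention-scoring exercise: for each genotype,
#' `images_per_genotype` images get a latent positive-cell proportion
#' drawn by perturbing the genotype's true proportion on the logit scale
#' with SD `image_sd` (image-to-image heterogeneity); each participant
#' then independently counts `cells_per_image` cells per image, with the
#' positive count binomial at the image's latent proportion.  All
#' participants score the same images, sharing the latent proportions but
#' not the counting noise.  Deterministic given `seed`.
#'
#' @param n_participants Number of blinded raters (default 3).
#' @param images_per_genotype Number of images per genotype (default 25).
#' @param cells_per_image Cells counted per image (default 12).
#' @param true_proportion Named numeric vector of true positive-cell
#'   proportions per genotype, each in (0, 1); defaults to the
#'   wild-type / heterozygote / homozygote retention levels 0.34, 0.64,
#'   0.83.
#' @param image_sd Logit-scale SD of the image-level perturbation
#'   (default 0.5); 0 removes image heterogeneity.
#' @param seed Optional RNG seed.
#' @return A [rater_counts()] table.
#' @export
simulate_rater_counts <- function(n_participants = 3L,
                                  images_per_genotype = 25L,
                                  cells_per_image = 12L,
                                  true_proportion = c(WT = 0.34, HET = 0.64,
                                                      HOM = 0.83),
                                  image_sd = 0.5,
                                  seed = NULL) {
  .assert(all(true_proportion > 0 & true_proportion < 1),
          "apms_validation_error", "true proportions must lie in (0, 1)")
  .assert(image_sd >= 0, "apms_validation_error", "image_sd must be >= 0")
  .assert(!is.null(names(true_proportion)), "apms_validation_error",
          "true_proportion must be named by genotype")
  .with_seed(seed, {
    recs <- lapply(names(true_proportion), function(g) {
      logit <- log(true_proportion[[g]] / (1 - true_proportion[[g]]))
      lat <- stats::plogis(logit + stats::rnorm(images_per_genotype, 0, image_sd))
      img <- sprintf("%s_img%03d", g, seq_len(images_per_genotype))
      do.call(rbind, lapply(seq_len(n_participants), function(pp) {
        data.frame(participant = sprintf("rater%d", pp),
                   image = img, genotype = g,
                   positive = stats::rbinom(images_per_genotype,
                                            cells_per_image, lat),
                   total = cells_per_image,
                   stringsAsFactors = FALSE)
      }))
    })
    tab <- do.call(rbind, recs)
    rater_counts(tab$participant, tab$image, tab$genotype, tab$positive,
                 tab$total)
  })
}

#' Empirical FDR and power of the full discovery pipeline
#'
#' Monte-Carlo harness validating that the complete pipeline -- negative
#' control filter, bait normalization, fold enrichment, log2-scale
#' homoscedastic t-test, two-stage step-up FDR at `q_target` -- controls
#' the false discovery rate on data with known truth.  Each replicate
#' draws a fresh [simulate_apms()] dataset (per-replicate seed =
#' `master_seed + replicate`, a simple counter scheme), runs
#' [run_pipeline()], and counts false positives (rejected proteins whose
#' true class is not `DIFFERENTIAL`) among the rejections.  The empirical
#' FDR is the mean over replicates of `FP / max(R, 1)`; power is the mean
#' fraction of planted `DIFFERENTIAL` proteins rejected.
#'
#' @param config An [apms_sim_config()]; its `seed` field is overridden
#'   per replicate.
#' @param reps Number of simulation replicates.
#' @param q_target Desired FDR level passed to the pipeline (default 0.10).
#' @param master_seed Integer seed from which per-replicate seeds are
#'   derived.
#' @return List with `fdr`, `fdr_se`, `power`, `power_se` (Monte-Carlo
#'   standard errors) and `per_rep`, a data frame with per-replicate
#'   counts (`n_tested`, `n_rejected`, `fp`, `tp`, `fdp`).
#' @export
fdr_simulation <- function(config = apms_sim_config(), reps = 500L,
                           q_target = 0.10, master_seed = 1L) {
  stopifnot(inherits(config, "apms_sim_config"))
  reps <- as.integer(reps)
  .assert(reps >= 1L, "apms_validation_error", "reps must be >= 1")
  pc <- pipeline_config(log_transform = TRUE, q_target = q_target)
  per <- vector("list", reps)
  for (i in seq_len(reps)) {
    cfg <- config
    cfg$seed <- master_seed + i
    sim <- simulate_apms(cfg)
    tab <- run_pipeline(sim$abundance, sim$layout, pc)
    truth <- sim$truth
    cls <- truth$class[match(tab$protein, truth$protein)]
    rej <- tab$significant
    fp <- sum(rej & cls != "DIFFERENTIAL")
    tp <- sum(rej & cls == "DIFFERENTIAL")
    n_diff <- sum(truth$class == "DIFFERENTIAL")
    per[[i]] <- data.frame(rep = i, seed = cfg$seed,
                           n_tested = nrow(tab),
                           n_rejected = sum(rej), fp = fp, tp = tp,
                           fdp = fp / max(sum(rej), 1L),
                           tpr = if (n_diff > 0L) tp / n_diff else NA_real_)
  }
  per <- do.call(rbind, per)
  list(fdr = mean(per$fdp),
       fdr_se = stats::sd(per$fdp) / sqrt(reps),
       power = mean(per$tpr),
       power_se = stats::sd(per$tpr) / sqrt(reps),
       q_target = q_target,
       reps = reps,
       per_rep = per)
}
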