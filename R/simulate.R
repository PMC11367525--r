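#' Configuration for the paired-omics simulator
#'
#' The defaults emulate the experimental design of an early-development
#' time course in *D. discoideum*: 24 RNA libraries (4 replicates at
#' 0,2,4,6,8,10 h) and 15 protein samples (3 replicates at 0,2,4,8,10 h),
#' where protein replicate r at time t shares a plate with RNA replicate r at
#' the same time. Protein follows mRNA through first-order kinetics
#' dP/dt = alpha*M(t) - delta*P, so the effective translation lag is ~1/delta
#' hours; the default delta range brackets 1/3 per hour (a 2-4 h lag).
#'
#' @param n_genes Number of genes.
#' @param archetype_mix Named proportions over the trajectory archetypes
#'   `linear_up`, `linear_down`, `dip_recover`, `spike_decay`, `flat`;
#'   must sum to 1.
#' @param time_grid_rna,time_grid_protein Sampling times in hours, ascending,
#'   starting at 0. Protein times must be a subset of RNA times (same-plate
#'   pairing).
#' @param n_reps_rna,n_reps_protein Replicates per time point.
#' @param nb_dispersion Negative-binomial overdispersion phi in
#'   var = mu + phi*mu^2 (scalar or per-gene).
#' @param lib_size_range Uniform range of sequencing library sizes (reads).
#' @param alpha_range Protein synthesis rate range (per hour).
#' @param delta_range Protein degradation rate range (per hour).
#' @param intensity_noise_sd Log2-scale s.d. of protein measurement noise.
#' @param mnar_midpoint,mnar_slope Logistic intensity-dependent censoring:
#'   a cell with log2-intensity x is missing with probability
#'   1/(1+exp(slope*(x-midpoint))). `mnar_midpoint` may be a vector with one
#'   value per protein time point to make the detection limit drift over the
#'   course (e.g. harsher censoring late in development).
#' @param plate_effect_sd Log2-scale s.d. of the per-gene biological effect
#'   shared by the RNA and protein sample from one plate.
#' @param intensity_scale Multiplier turning protein fractions into
#'   intensity units before the log (parts-per-million by default).
#' @param seed Integer seed; fully determines a run.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       archetype_mix = c(linear_up = 0.25, linear_down = 0.25,
                                         dip_recover = 0.15,
                                         spike_decay = 0.15, flat = 0.20),
                       time_grid_rna = c(0, 2, 4, 6, 8, 10),
                       time_grid_protein = c(0, 2, 4, 8, 10),
                       n_reps_rna = 4, n_reps_protein = 3,
                       nb_dispersion = 0.05,
                       lib_size_range = c(8e5, 1.2e6),
                       alpha_range = c(0.5, 2),
                       delta_range = c(0.2, 0.5),
                       intensity_noise_sd = 0.25,
                       mnar_midpoint = 6, mnar_slope = 1,
                       plate_effect_sd = 0.15,
                       intensity_scale = 1e6,
                       seed = 1L) {
  known <- c("linear_up", "linear_down", "dip_recover", "spike_decay", "flat")
  .check(all(names(archetype_mix) %in% known),
         "unknown archetype name(s): %s",
         paste(setdiff(names(archetype_mix), known), collapse = ", "))
  .check(abs(sum(archetype_mix) - 1) < 1e-8, "archetype_mix must sum to 1")
  .check(all(archetype_mix >= 0), "archetype_mix proportions must be >= 0")
  for (g in list(time_grid_rna, time_grid_protein)) {
    .check(!is.unsorted(g, strictly = TRUE), "time grids must be ascending")
    .check(g[1] == 0, "time grids must include 0")
  }
  .check(n_genes >= 0 && n_reps_rna >= 1 && n_reps_protein >= 1,
         "counts must be non-negative")
  .check(all(alpha_range > 0) && all(delta_range > 0),
         "kinetic rates must be > 0")
  .check(all(nb_dispersion >= 0), "nb_dispersion must be >= 0")
  .check(intensity_noise_sd >= 0 && plate_effect_sd >= 0,
         "noise s.d. must be >= 0")
  .check(length(mnar_midpoint) %in% c(1L, length(time_grid_protein)),
         "mnar_midpoint must be scalar or one value per protein time point")
  structure(list(n_genes = as.integer(n_genes),
                 archetype_mix = archetype_mix,
                 time_grid_rna = time_grid_rna,
                 time_grid_protein = time_grid_protein,
                 n_reps_rna = as.integer(n_reps_rna),
                 n_reps_protein = as.integer(n_reps_protein),
                 nb_dispersion = nb_dispersion,
                 lib_size_range = lib_size_range,
                 alpha_range = alpha_range, delta_range = delta_range,
                 intensity_noise_sd = intensity_noise_sd,
                 mnar_midpoint = mnar_midpoint, mnar_slope = mnar_slope,
                 plate_effect_sd = plate_effect_sd,
                 intensity_scale = intensity_scale,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# dense-grid step; the RK4 step is 2x this so half-steps fall on the grid
.sim_dt <- 0.05

#' Simulate archetypal mRNA trajectories
#'
#' Draws an archetype per gene and evaluates its continuous trajectory M(t)
#' on a dense grid. `linear_up`/`linear_down` are exponential ramps
#' M(t) = M0*exp(k*t); `dip_recover` is a smooth U-shape with its extremum
#' near mid-course; `spike_decay` changes sharply between 0 and 2 h and then
#' relaxes back; `flat` is constant. Baseline abundances M0 are log-normal.
#'
#' Uses the current RNG stream; [generate_paired_dataset()] seeds it from the
#' configuration.
#'
#' @param config A [sim_config()].
#' @return Object of class `true_trajectories`: list with `time` (dense hour
#'   grid), `M` (gene x time matrix), and `params` (per-gene data frame with
#'   archetype, M0, rate `k`, amplitude `amp`).
#' @export
simulate_mrna_profiles <- function(config) {
  t_max <- max(config$time_grid_rna, config$time_grid_protein)
  time <- seq(0, t_max, by = .sim_dt)
  n <- config$n_genes
  arch <- if (n > 0)
    sample(names(config$archetype_mix), n, replace = TRUE,
           prob = config$archetype_mix) else character(0)
  M0 <- stats::rlnorm(n, meanlog = log(100), sdlog = 1)
  k <- numeric(n)
  amp <- numeric(n)
  k[arch == "linear_up"] <- stats::runif(sum(arch == "linear_up"), 0.10, 0.30)
  k[arch == "linear_down"] <- -stats::runif(sum(arch == "linear_down"),
                                            0.10, 0.30)
  amp[arch == "dip_recover"] <- stats::runif(sum(arch == "dip_recover"),
                                             0.8, 1.6)
  amp[arch == "spike_decay"] <- stats::runif(sum(arch == "spike_decay"),
                                             0.8, 1.6) *
    sample(c(-1, 1), sum(arch == "spike_decay"), replace = TRUE)
  M <- matrix(0, nrow = n, ncol = length(time),
              dimnames = list(if (n > 0) sprintf("gene_%04d", seq_len(n))
                              else NULL, NULL))
  tm <- t_max / 2  # dip extremum near mid-course
  for (i in seq_len(n)) {
    M[i, ] <- switch(arch[i],
      flat = rep(M0[i], length(time)),
      linear_up = ,
      linear_down = M0[i] * exp(k[i] * time),
      dip_recover = M0[i] * exp(-amp[i] * exp(-(time - tm)^2 / (2 * 2^2))),
      spike_decay = M0[i] * exp(amp[i] * (time / 1) * exp(1 - time / 1)))
  }
  params <- data.frame(gene_id = rownames(M) %||% character(0),
                       archetype = arch, M0 = M0, k = k, amp = amp,
                       stringsAsFactors = FALSE)
  structure(list(time = time, M = M, params = params),
            class = "true_trajectories")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Integrate protein trajectories from mRNA trajectories
#'
#' Solves dP/dt = alpha*M(t) - delta*P per gene with fixed-step RK4 (0.1 h
#' steps; M is tabulated at half-steps so no interpolation error enters).
#' P(0) is initialised at the pre-starvation steady state alpha*M(0)/delta,
#' so a constant M stays at equilibrium and any change in M reaches the
#' protein with an effective lag of about 1/delta hours.
#'
#' @param traj `true_trajectories` from [simulate_mrna_profiles()].
#' @param alpha Synthesis rate(s), per hour (recycled over genes).
#' @param delta Degradation rate(s), per hour; must be > 0.
#' @return `traj` with matrix `P` and per-gene `alpha`, `delta` added.
#' @export
protein_from_mrna <- function(traj, alpha, delta) {
  .check(all(delta > 0), "delta must be > 0")
  n <- nrow(traj$M)
  alpha <- rep_len(alpha, n)
  delta <- rep_len(delta, n)
  nt <- length(traj$time)
  P <- matrix(0, nrow = n, ncol = nt, dimnames = dimnames(traj$M))
  if (n > 0) {
    P[, 1] <- alpha * traj$M[, 1] / delta
    h <- 2 * .sim_dt
    f <- function(p, m) alpha * m - delta * p
    # RK4 over pairs of dense-grid intervals; odd grid points by one extra
    # half-size RK4 step at the end if nt is even
    i <- 1L
    while (i + 2L <= nt) {
      m0 <- traj$M[, i]; mh <- traj$M[, i + 1L]; m1 <- traj$M[, i + 2L]
      p <- P[, i]
      k1 <- f(p, m0)
      k2 <- f(p + h / 2 * k1, mh)
      k3 <- f(p + h / 2 * k2, mh)
      k4 <- f(p + h * k3, m1)
      P[, i + 2L] <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      # fill the intermediate point with a half-step RK4 (for dense output)
      hh <- .sim_dt
      mq <- (m0 + mh) / 2
      k1s <- k1
      k2s <- f(p + hh / 2 * k1s, mq)
      k3s <- f(p + hh / 2 * k2s, mq)
      k4s <- f(p + hh * k3s, mh)
      P[, i + 1L] <- p + hh / 6 * (k1s + 2 * k2s + 2 * k3s + k4s)
      i <- i + 2L
    }
    if (i < nt) {  # one trailing half step
      hh <- .sim_dt
      p <- P[, i]
      m0 <- traj$M[, i]; m1 <- traj$M[, i + 1L]
      mq <- (m0 + m1) / 2
      k1 <- f(p, m0)
      k2 <- f(p + hh / 2 * k1, mq)
      k3 <- f(p + hh / 2 * k2, mq)
      k4 <- f(p + hh * k3, m1)
      P[, i + 1L] <- p + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    P[P < 0] <- 0
  }
  traj$P <- P
  traj$alpha <- alpha
  traj$delta <- delta
  traj
}

# evaluate a dense-grid trajectory matrix at given hour(s)
.traj_at <- function(traj, what, t) {
  idx <- round(t / .sim_dt) + 1L
  .check(all(abs(t / .sim_dt - round(t / .sim_dt)) < 1e-9) &&
           all(idx >= 1L & idx <= length(traj$time)),
         "requested times not on the simulation grid")
  traj[[what]][, idx, drop = FALSE]
}

# RNA / protein sample tables implied by a config
.rna_samples <- function(config) {
  g <- expand.grid(replicate = seq_len(config$n_reps_rna),
                   time_h = config$time_grid_rna)
  paired <- g$time_h %in% config$time_grid_protein &
    g$replicate <= config$n_reps_protein
  sample_table(sample_id = sprintf("rna_%02dh_r%d", g$time_h, g$replicate),
               modality = "transcript", time_h = g$time_h,
               replicate = paste0("r", g$replicate),
               plate = ifelse(paired,
                              sprintf("plate_%02dh_r%d", g$time_h,
                                      g$replicate), NA))
}

.protein_samples <- function(config) {
  g <- expand.grid(replicate = seq_len(config$n_reps_protein),
                   time_h = config$time_grid_protein)
  sample_table(sample_id = sprintf("prot_%02dh_r%d", g$time_h, g$replicate),
               modality = "protein", time_h = g$time_h,
               replicate = paste0("r", g$replicate),
               plate = sprintf("plate_%02dh_r%d", g$time_h, g$replicate))
}

#' Draw negative-binomial counts from true mRNA trajectories
#'
#' Count for gene g in sample s is NB with mean
#' libsize_s * M_g(t_s) / sum_g M_g(t_s) and variance mu + phi*mu^2
#' (Poisson when phi = 0). Uses the current RNG stream.
#'
#' @param traj `true_trajectories`.
#' @param config A [sim_config()].
#' @param samples Optional RNA sample table; defaults to the design implied
#'   by `config`.
#' @param plate_effects Optional gene x sample matrix of log2-scale effects
#'   multiplying the expected abundance (shared with the paired protein
#'   sample when generated by [generate_paired_dataset()]).
#' @return `omic_matrix` of raw counts.
#' @export
sample_counts <- function(traj, config, samples = NULL,
                          plate_effects = NULL) {
  if (is.null(samples)) samples <- .rna_samples(config)
  n <- nrow(traj$M)
  ns <- nrow(samples)
  lib <- stats::runif(ns, config$lib_size_range[1], config$lib_size_range[2])
  w <- .traj_at(traj, "M", samples$time_h)
  if (!is.null(plate_effects)) w <- w * 2^plate_effects
  phi <- rep_len(config$nb_dispersion, n)
  counts <- matrix(0, nrow = n, ncol = ns,
                   dimnames = list(rownames(traj$M), samples$sample_id))
  for (s in seq_len(ns)) {
    tot <- sum(w[, s])
    mu <- if (tot > 0) lib[s] * w[, s] / tot else rep(0, n)
    pois <- phi <= 1e-12
    if (any(pois)) counts[pois, s] <- stats::rpois(sum(pois), mu[pois])
    if (any(!pois)) counts[!pois, s] <-
      stats::rnbinom(sum(!pois), mu = mu[!pois], size = 1 / phi[!pois])
  }
  omic_matrix(counts, samples, "raw_count")
}

#' Draw protein log2-intensities from true protein trajectories
#'
#' log2-intensity = log2(scale * P_g(t_s)/sum_g P_g(t_s)) plus Gaussian
#' measurement noise plus the plate effect shared with the paired RNA sample.
#' Uses the current RNG stream.
#'
#' @inheritParams sample_counts
#' @return `omic_matrix` of complete (uncensored) log-intensities.
#' @export
sample_intensities <- function(traj, config, samples = NULL,
                               plate_effects = NULL) {
  if (is.null(samples)) samples <- .protein_samples(config)
  n <- nrow(traj$P)
  ns <- nrow(samples)
  w <- .traj_at(traj, "P", samples$time_h)
  vals <- matrix(-Inf, nrow = n, ncol = ns,
                 dimnames = list(rownames(traj$P), samples$sample_id))
  for (s in seq_len(ns)) {
    tot <- sum(w[, s])
    if (tot > 0) vals[, s] <- log2(w[, s] / tot * config$intensity_scale)
  }
  if (!is.null(plate_effects)) vals <- vals + plate_effects
  if (config$intensity_noise_sd > 0 && n > 0)
    vals <- vals + matrix(stats::rnorm(n * ns, 0, config$intensity_noise_sd),
                          n, ns)
  omic_matrix(vals, samples, "log_intensity")
}

#' Censor low intensities (missing not at random)
#'
#' Each cell with value x is set missing independently with probability
#' 1/(1 + exp(slope*(x - midpoint))): low values are the most likely to drop
#' out, emulating the detection limit of label-free proteomics.
#'
#' @param intensities `omic_matrix` of log-intensities.
#' @param config A [sim_config()] supplying `mnar_midpoint`, `mnar_slope`.
#' @param seed Optional seed; by default the current RNG stream is used.
#' @return `omic_matrix` with censored cells set to `NA` and the mask set.
#' @export
apply_mnar_censoring <- function(intensities, config, seed = NULL) {
  with_seed(seed, {
    x <- intensities$values
    mid <- config$mnar_midpoint
    if (length(mid) > 1L) {
      j <- match(intensities$samples$time_h, config$time_grid_protein)
      .check(!anyNA(j), "sample time points not in the protein time grid")
      mid <- matrix(mid[j], nrow(x), ncol(x), byrow = TRUE)
    }
    z <- config$mnar_slope * (x - mid)
    z[is.nan(z)] <- 0  # slope = Inf exactly at the midpoint: toss a coin
    p_miss <- 1 / (1 + exp(z))
    drop <- matrix(stats::runif(length(x)) < p_miss, nrow(x), ncol(x))
    x[drop] <- NA
    omic_matrix(x, intensities$samples, "log_intensity", missing = drop)
  })
}

#' Generate a complete paired transcriptomics/proteomics dataset
#'
#' Runs the whole generator under `config$seed`: archetypal mRNA
#' trajectories, kinetic protein trajectories, plate effects shared between
#' the RNA and protein sample from one plate, NB counts, noisy
#' log-intensities, and MNAR censoring. Identical configurations give
#' bit-identical datasets.
#'
#' @param config A [sim_config()].
#' @return A [paired_omics()] dataset with simulation truth attached.
#' @export
generate_paired_dataset <- function(config) {
  .check(all(config$time_grid_protein %in% config$time_grid_rna),
         "every protein time point must also be an RNA time point")
  with_seed(config$seed, {
    traj <- simulate_mrna_profiles(config)
    alpha <- stats::runif(config$n_genes, config$alpha_range[1],
                          config$alpha_range[2])
    delta <- stats::runif(config$n_genes, config$delta_range[1],
                          config$delta_range[2])
    traj <- protein_from_mrna(traj, alpha, delta)

    rs <- .rna_samples(config)
    ps <- .protein_samples(config)
    n <- config$n_genes

    plates <- unique(stats::na.omit(c(rs$plate, ps$plate)))
    pe_plate <- matrix(stats::rnorm(n * length(plates), 0,
                                    config$plate_effect_sd),
                       nrow = n, ncol = length(plates),
                       dimnames = list(rownames(traj$M), plates))
    pe_for <- function(tbl) {
      out <- matrix(0, nrow = n, ncol = nrow(tbl))
      for (j in seq_len(nrow(tbl))) {
        out[, j] <- if (!is.na(tbl$plate[j])) pe_plate[, tbl$plate[j]]
        else stats::rnorm(n, 0, config$plate_effect_sd)
      }
      out
    }
    counts <- sample_counts(traj, config, rs, pe_for(rs))
    intens <- sample_intensities(traj, config, ps, pe_for(ps))
    intens <- apply_mnar_censoring(intens, config)

    genes <- data.frame(gene_id = rownames(traj$M) %||% character(0),
                        is_protein_coding = rep(TRUE, n),
                        protein_group = rownames(traj$M) %||% character(0),
                        stringsAsFactors = FALSE)
    tt <- sort(unique(c(config$time_grid_rna, config$time_grid_protein)))
    truth <- cbind(traj$params,
                   alpha = alpha, delta = delta,
                   stats::setNames(as.data.frame(.traj_at(traj, "M", tt)),
                                   sprintf("M_%gh", tt)),
                   stats::setNames(as.data.frame(.traj_at(traj, "P", tt)),
                                   sprintf("P_%gh", tt)))
    rownames(truth) <- NULL
    paired_omics(counts, intens, genes, truth = truth, config = config)
  })
}
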