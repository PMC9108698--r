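# Synthetic serial TRB cohorts. The generator emulates the statistical
# structure the analysis assumes: heavy-tailed clone-size laws with a
# persistent dominant expansion for PLHIV-like repertoires, near-uniform
# naive-like structure for controls, convergent recombination (several
# nucleotide rearrangements per amino-acid clonotype), CDR3 length spectra,
# AR(1) persistence of clone frequencies across serial timepoints, gradual
# post-ART contraction of expansions plus influx of new naive-like clones,
# a step drop in viral load and saturating CD4 recovery at ART initiation,
# and edit-distance-1 sequence neighborhoods.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.V_GENES <- c("TRBV19", "TRBV05-1", "TRBV06-5", "TRBV07-9", "TRBV20-1",
              "TRBV27", "TRBV28", "TRBV09", "TRBV12-3", "TRBV04-1")
.J_GENES <- c("TRBJ2-1", "TRBJ2-7", "TRBJ1-1", "TRBJ1-2", "TRBJ2-3",
              "TRBJ2-5")
.HLA_POOL <- list(
  A = c("HLA-A*01:01:01", "HLA-A*02:01:01", "HLA-A*03:01:01",
        "HLA-A*11:01:01", "HLA-A*24:02:01"),
  B = c("HLA-B*07:02:01", "HLA-B*08:01:01", "HLA-B*44:02:01",
        "HLA-B*44:03:01", "HLA-B*57:01:01", "HLA-B*35:01:01"),
  C = c("HLA-C*04:01:01", "HLA-C*05:01:01", "HLA-C*07:01:01",
        "HLA-C*16:01:01"))

# reverse genetic code (amino acid -> codons), padded into a matrix for
# vectorized back-translation; derived once from the standard code
.codon_env <- new.env(parent = emptyenv())
.codon_tables <- function() {
  if (is.null(.codon_env$mat)) {
    gc <- Biostrings::GENETIC_CODE
    by_aa <- split(names(gc), unname(gc))
    aas <- names(by_aa)
    maxc <- max(lengths(by_aa))
    mat <- matrix(NA_character_, length(aas), maxc, dimnames = list(aas, NULL))
    for (i in seq_along(aas)) mat[i, seq_along(by_aa[[i]])] <- by_aa[[i]]
    .codon_env$mat <- mat
    .codon_env$ncod <- lengths(by_aa)
    .codon_env$aas <- aas
  }
  .codon_env
}

# Random synonymous back-translation of amino-acid strings ('*' maps to a
# stop codon), one nucleotide sequence per input element.
back_translate <- function(aa) {
  if (!length(aa)) return(character(0))
  ct <- .codon_tables()
  lens <- nchar(aa)
  chars <- unlist(strsplit(aa, ""), use.names = FALSE)
  ai <- match(chars, ct$aas)
  if (anyNA(ai)) stop("cannot back-translate character: ",
                      chars[which(is.na(ai))[1]])
  pick <- ceiling(runif(length(ai)) * ct$ncod[ai])
  cods <- ct$mat[cbind(ai, pick)]
  grp <- factor(rep(seq_along(aa), lens), levels = seq_along(aa))
  unname(vapply(split(cods, grp), paste, "", collapse = ""))
}

# n random CDR3 AA sequences: conserved C...F, middle uniform over the 20
# amino acids, lengths from a discretized normal truncated to [6, 27]
random_cdr3_aa <- function(n, length_mean, length_sd) {
  if (!n) return(character(0))
  L <- pmin(27L, pmax(6L, as.integer(round(rnorm(n, length_mean, length_sd)))))
  m <- L - 2L
  chars <- sample(.AA20, sum(m), replace = TRUE)
  grp <- factor(rep(seq_len(n), m), levels = seq_len(n))
  paste0("C", unname(vapply(split(chars, grp), paste, "", collapse = "")), "F")
}

#' Synthetic cohort generator configuration
#'
#' Defaults encode the two repertoire archetypes the package analyses.
#' The "plhiv" profile: 30 participants sampled serially (5-11 timepoints,
#' ART starting before the third sample), 20,000 clones following a Zipf
#' clone-size law with a dominant expansion holding 12% of the repertoire,
#' reduced convergent recombination (1.1 nucleotide variants per AA
#' clonotype), a slightly shorter and narrower CDR3 length spectrum, strong
#' clone persistence across timepoints, and post-ART diversification (5%
#' new naive-like clones per timepoint) with gradual contraction of
#' expanded clones. The "control" profile: 189 single-timepoint
#' participants, 40,000 clones with near-even sizes, higher production
#' efficiency (1.3), median CDR3 length 15 AA and denser edit-distance-1
#' sequence neighborhoods. Sequencing depth defaults to 50,000 templates
#' per sample in both profiles.
#'
#' @param profile "plhiv" or "control"; fills all unset arguments.
#' @param n_participants number of participants.
#' @param samples_per_participant integer range `c(min, max)`.
#' @param art_sample_index timepoint index at which ART starts (the ART
#'   date falls just before this sample); NA for controls.
#' @param n_clones clones per participant pool.
#' @param clone_law "uniform", or `list(type = "dirichlet", alpha = )`, or
#'   `list(type = "powerlaw", exponent = )` where `exponent` is the
#'   clone-size-distribution exponent (2 gives the classic Zipf rank law).
#' @param dominant_clone_freq repertoire fraction held by the single
#'   dominant expansion (0 disables it).
#' @param convergence_rate mean nucleotide variants per AA clonotype
#'   (>= 1); variant numbers are 1 + Poisson(rate - 1).
#' @param length_mean,length_sd CDR3 AA length distribution (discretized
#'   normal truncated to \[6, 27\]).
#' @param persistence AR(1) autocorrelation of clone log-frequency noise
#'   across timepoints, in \[0, 1\].
#' @param post_art_diversification fraction of `n_clones` added as new
#'   naive-like clones at each post-ART timepoint.
#' @param post_art_contraction per-timepoint multiplicative shrinkage of
#'   expanded-clone log-weight deviations after ART (0 disables).
#' @param freq_log_sd stationary SD of the clone log-frequency noise.
#' @param neighbor_rate fraction of clones generated as single-substitution
#'   variants of a previously generated clone (creates the edit-distance-1
#'   neighborhoods real repertoires show).
#' @param total_count_per_sample templates per sample.
#' @param seed integer master seed; every draw derives from it.
#' @return object of class `trb_generator_config`.
#' @export
generator_config <- function(profile = c("plhiv", "control"),
                             n_participants = NULL,
                             samples_per_participant = NULL,
                             art_sample_index = NULL,
                             n_clones = NULL,
                             clone_law = NULL,
                             dominant_clone_freq = NULL,
                             convergence_rate = NULL,
                             length_mean = NULL,
                             length_sd = NULL,
                             persistence = NULL,
                             post_art_diversification = NULL,
                             post_art_contraction = NULL,
                             freq_log_sd = NULL,
                             neighbor_rate = NULL,
                             total_count_per_sample = NULL,
                             seed = 1) {
  profile <- match.arg(profile)
  def <- if (profile == "plhiv") {
    list(n_participants = 30L, samples_per_participant = c(5L, 11L),
         art_sample_index = 3L, n_clones = 20000L,
         clone_law = list(type = "powerlaw", exponent = 2),
         dominant_clone_freq = 0.12, convergence_rate = 1.1,
         length_mean = 14.3, length_sd = 1.6, persistence = 0.9,
         post_art_diversification = 0.05, post_art_contraction = 0.08,
         freq_log_sd = 0.4, neighbor_rate = 0.15,
         total_count_per_sample = 50000L)
  } else {
    list(n_participants = 189L, samples_per_participant = c(1L, 1L),
         art_sample_index = NA_integer_, n_clones = 40000L,
         clone_law = list(type = "dirichlet", alpha = 1),
         dominant_clone_freq = 0, convergence_rate = 1.3,
         length_mean = 15, length_sd = 2, persistence = 1,
         post_art_diversification = 0, post_art_contraction = 0,
         freq_log_sd = 0.4, neighbor_rate = 0.35,
         total_count_per_sample = 50000L)
  }
  override <- list(n_participants = n_participants,
                   samples_per_participant = samples_per_participant,
                   art_sample_index = art_sample_index,
                   n_clones = n_clones, clone_law = clone_law,
                   dominant_clone_freq = dominant_clone_freq,
                   convergence_rate = convergence_rate,
                   length_mean = length_mean, length_sd = length_sd,
                   persistence = persistence,
                   post_art_diversification = post_art_diversification,
                   post_art_contraction = post_art_contraction,
                   freq_log_sd = freq_log_sd, neighbor_rate = neighbor_rate,
                   total_count_per_sample = total_count_per_sample)
  for (nm in names(override)) {
    if (!is.null(override[[nm]])) def[[nm]] <- override[[nm]]
  }
  cfg <- def
  cfg$profile <- profile
  cfg$seed <- as.integer(seed)
  if (is.character(cfg$clone_law)) cfg$clone_law <- list(type = cfg$clone_law)
  stopifnot(cfg$n_clones >= 1,
            cfg$convergence_rate >= 1,
            cfg$persistence >= 0, cfg$persistence <= 1,
            cfg$dominant_clone_freq >= 0, cfg$dominant_clone_freq < 1,
            cfg$post_art_diversification >= 0,
            cfg$post_art_diversification <= 1,
            cfg$post_art_contraction >= 0, cfg$post_art_contraction < 1,
            cfg$neighbor_rate >= 0, cfg$neighbor_rate < 1,
            cfg$total_count_per_sample >= 1,
            length(cfg$samples_per_participant) == 2,
            cfg$clone_law$type %in% c("uniform", "dirichlet", "powerlaw"))
  if (cfg$clone_law$type == "powerlaw" &&
      (is.null(cfg$clone_law$exponent) || cfg$clone_law$exponent <= 1)) {
    stop("powerlaw clone law needs exponent > 1")
  }
  cfg$samples_per_participant <- as.integer(cfg$samples_per_participant)
  cfg$art_sample_index <- as.integer(cfg$art_sample_index)
  structure(cfg, class = "trb_generator_config")
}

#' Clinical trajectory configuration
#'
#' Viral load steps down immediately at ART initiation; the CD4 count
#' recovers along a saturating exponential toward a plateau that, as in
#' long-term observational cohorts, sits below the 700-1800 cells/uL
#' normal range.
#'
#' @param pre_art_viral_load log10 copies/mL range before ART.
#' @param post_art_viral_load log10 copies/mL under suppression.
#' @param cd4_start cells/uL at ART start.
#' @param cd4_plateau asymptotic cells/uL (>= cd4_start).
#' @param cd4_recovery_rate per-year rate of the saturating recovery.
#' @param noise_sd per-measurement CD4 noise (cells/uL).
#' @param vl_noise_sd per-measurement viral-load noise (log10).
#' @return object of class `trb_clinical_config`.
#' @export
clinical_config <- function(pre_art_viral_load = c(4.5, 5.5),
                            post_art_viral_load = 1.6,
                            cd4_start = 250,
                            cd4_plateau = 650,
                            cd4_recovery_rate = 0.35,
                            noise_sd = 40,
                            vl_noise_sd = 0.15) {
  stopifnot(cd4_plateau >= cd4_start, all(pre_art_viral_load >= 0),
            post_art_viral_load >= 0, length(pre_art_viral_load) == 2)
  structure(list(pre_art_viral_load = pre_art_viral_load,
                 post_art_viral_load = post_art_viral_load,
                 cd4_start = cd4_start, cd4_plateau = cd4_plateau,
                 cd4_recovery_rate = cd4_recovery_rate,
                 noise_sd = noise_sd, vl_noise_sd = vl_noise_sd),
            class = "trb_clinical_config")
}

.base_weights <- function(cfg, n) {
  law <- cfg$clone_law
  w <- switch(law$type,
              uniform = rep(1, n),
              dirichlet = {
                a <- if (is.null(law$alpha)) 1 else law$alpha
                pmax(rgamma(n, shape = a, rate = 1), 1e-12)
              },
              powerlaw = seq_len(n)^(-1 / (law$exponent - 1)))
  w / sum(w)
}

.mutate_cdr3 <- function(s) {
  L <- nchar(s)
  p <- if (L <= 3) 2L else sample(2:(L - 1), 1)
  old <- substr(s, p, p)
  repl <- sample(.AA20[.AA20 != old], 1)
  paste0(substr(s, 1, p - 1), repl, substr(s, p + 1, L))
}

# Clone pool for one participant: AA sequences (with edit-1 neighborhoods),
# nucleotide variants, base weights, post-ART birth times, gene calls.
.build_pool <- function(cfg) {
  t_max <- cfg$samples_per_participant[2]
  n_core <- cfg$n_clones
  post_max <- if (is.na(cfg$art_sample_index)) 0L
              else max(0L, t_max - cfg$art_sample_index + 1L)
  n_new <- round(cfg$post_art_diversification * n_core)
  n_total <- n_core + post_max * n_new
  fresh <- random_cdr3_aa(n_total, cfg$length_mean, cfg$length_sd)
  is_mut <- runif(n_total) < cfg$neighbor_rate
  is_mut[1] <- FALSE
  seqs <- character(n_total)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n_total)) {
    s <- if (is_mut[i]) .mutate_cdr3(seqs[sample.int(i - 1L, 1L)]) else fresh[i]
    while (exists(s, envir = seen, inherits = FALSE)) {
      s <- random_cdr3_aa(1L, cfg$length_mean, cfg$length_sd)
    }
    seqs[i] <- s
    assign(s, TRUE, envir = seen)
  }
  # convergent recombination: 1 + Poisson(rate - 1) nt variants per clone
  k <- 1L + rpois(n_total, cfg$convergence_rate - 1)
  clone_of <- rep(seq_len(n_total), k)
  nt <- back_translate(seqs[clone_of])
  for (round in 1:5) {
    dup <- duplicated(paste(clone_of, nt))
    if (!any(dup)) break
    nt[dup] <- back_translate(seqs[clone_of[dup]])
  }
  dup <- duplicated(paste(clone_of, nt))
  if (any(dup)) {
    clone_of <- clone_of[!dup]
    nt <- nt[!dup]
  }
  u <- rexp(length(nt))
  tot_u <- rowsum(u, clone_of)[, 1]
  share <- u / tot_u[clone_of]
  w_core <- if (cfg$dominant_clone_freq > 0) {
    c(cfg$dominant_clone_freq,
      .base_weights(cfg, n_core - 1L) * (1 - cfg$dominant_clone_freq))
  } else {
    .base_weights(cfg, n_core)
  }
  w_new <- if (n_total > n_core) {
    rep(unname(quantile(w_core, 0.5)), n_total - n_core)
  } else {
    numeric(0)
  }
  birth <- c(rep(0L, n_core),
             if (post_max > 0) rep(cfg$art_sample_index + seq_len(post_max) - 1L,
                                   each = n_new))
  list(seqs = seqs, base_w = c(w_core, w_new), birth = birth,
       clone_of = clone_of, nt = nt, share = share,
       v_gene = sample(.V_GENES, length(nt), replace = TRUE),
       j_gene = sample(.J_GENES, length(nt), replace = TRUE),
       n_core = n_core)
}

# Per-timepoint true clone frequencies: AR(1) log-noise with
# autocorrelation `persistence`, post-ART contraction of log-weight
# deviations, and activation of post-ART naive influx clones.
.timepoint_weights <- function(pool, cfg, t_max) {
  b <- log(pool$base_w)
  N <- length(b)
  rho <- cfg$persistence
  sdv <- cfg$freq_log_sd
  e <- matrix(0, N, t_max)
  e[, 1] <- rnorm(N, 0, sdv)
  if (t_max > 1) {
    for (t in 2:t_max) {
      e[, t] <- if (rho >= 1) e[, t - 1]
                else rho * e[, t - 1] + sqrt(1 - rho^2) * rnorm(N, 0, sdv)
    }
  }
  art <- cfg$art_sample_index
  core <- pool$birth == 0L
  mb <- mean(b[core])
  W <- matrix(0, N, t_max)
  for (t in seq_len(t_max)) {
    d <- if (!is.na(art) && t >= art) {
      (1 - cfg$post_art_contraction)^(t - art + 1)
    } else 1
    lw <- mb + d * (b - mb) + e[, t]
    active <- pool$birth <= t
    w <- exp(lw) * as.numeric(active)
    W[, t] <- w / sum(w)
  }
  W
}

# All repertoires (timepoints 1..t_max) for one participant; the RNG
# stream is fully determined by (config seed, participant id), so a
# repertoire is identical whether generated standalone or within a cohort.
.generate_participant <- function(cfg, participant_id) {
  with_seed(derive_seed(cfg$seed, hash_id(participant_id), 1), {
    rng_n <- cfg$samples_per_participant
    n_samp <- if (rng_n[1] == rng_n[2]) rng_n[1]
              else sample(seq(rng_n[1], rng_n[2]), 1)
    mhc <- unlist(lapply(.HLA_POOL, sample, size = 2, replace = FALSE),
                  use.names = FALSE)
    t_max <- cfg$samples_per_participant[2]
    pool <- .build_pool(cfg)
    W <- .timepoint_weights(pool, cfg, t_max)
    base_date <- as.Date("2004-01-15") + 37 * (hash_id(participant_id) %% 200)
    dates <- base_date + 183 * (seq_len(t_max) - 1)
    art_date <- if (is.na(cfg$art_sample_index)) as.Date(NA)
                else dates[cfg$art_sample_index] - 30
    reps <- vector("list", t_max)
    for (t in seq_len(t_max)) {
      vw <- W[pool$clone_of, t] * pool$share
      cnt <- rmultinom(1, cfg$total_count_per_sample, vw)[, 1]
      keep <- cnt > 0
      reps[[t]] <- repertoire(
        data.frame(cdr3_nt = pool$nt[keep],
                   cdr3_aa = pool$seqs[pool$clone_of[keep]],
                   v_gene = pool$v_gene[keep],
                   j_gene = pool$j_gene[keep],
                   productive = TRUE,
                   count = cnt[keep],
                   stringsAsFactors = FALSE),
        sample_id = sprintf("%s_T%02d", participant_id, t),
        participant_id = participant_id,
        collection_date = dates[t])
    }
    n_active <- vapply(seq_len(t_max), function(t)
      sum(pool$birth == 0L | pool$birth <= t), 0L)
    dominant <- pool$seqs[which.max(pool$base_w)]
    list(reps = reps, n_samp = n_samp, dates = dates, art_date = art_date,
         mhc = mhc, n_active = n_active, dominant = dominant)
  })
}

#' Generate one synthetic repertoire
#'
#' Draws the repertoire of `participant_id` at the given timepoint under
#' the generator model: clone frequencies follow the configured clone-size
#' law (evolving across timepoints with AR(1) persistence), template counts
#' are multinomial at `total_count_per_sample`, each amino-acid clonotype
#' carries `1 + Poisson(convergence_rate - 1)` synonymous nucleotide
#' variants, and CDR3s start with the conserved cysteine and end with the
#' conserved phenylalanine. Fully reproducible: the same configuration and
#' identifiers give a bit-identical repertoire, standalone or inside
#' [generate_cohort()].
#'
#' @param config a [generator_config()].
#' @param participant_id character identifier.
#' @param timepoint sample index (1-based, at most
#'   `max(samples_per_participant)`).
#' @return a `trb_repertoire`.
#' @export
generate_repertoire <- function(config, participant_id = "P001",
                                timepoint = 1) {
  t_max <- config$samples_per_participant[2]
  if (timepoint < 1 || timepoint > t_max) {
    stop("timepoint must lie in 1..", t_max)
  }
  .generate_participant(config, participant_id)$reps[[timepoint]]
}

#' Generate a synthetic cohort
#'
#' Serial repertoires per participant with persistent dominant clones
#' established before ART and retained afterwards, post-ART influx of
#' naive-like clones and contraction of expansions, clinical trajectories
#' (step drop in viral load at ART initiation, saturating CD4 recovery)
#' and MHC genotypes. Group labels follow the cohort convention (pre-ART
#' iff the sample precedes the ART date; control participants have no ART
#' date). The returned cohort carries generator ground truth in `$truth`
#' (dominant clone, number of live clones per timepoint, spiked records).
#'
#' @param gen_config a [generator_config()].
#' @param clin_config a [clinical_config()]; ignored for the control
#'   profile.
#' @return a `trb_cohort`.
#' @export
generate_cohort <- function(gen_config, clin_config = clinical_config()) {
  n <- gen_config$n_participants
  prefix <- if (gen_config$profile == "plhiv") 1000 else 5000
  pids <- sprintf("%d", prefix + seq_len(n))
  reps <- list()
  parts <- vector("list", n)
  mhc <- list()
  clin <- vector("list", n)
  truth <- list(participants = list(), spikes = NULL)
  for (i in seq_len(n)) {
    p <- .generate_participant(gen_config, pids[i])
    take <- seq_len(p$n_samp)
    reps <- c(reps, p$reps[take])
    parts[[i]] <- data.frame(participant_id = pids[i],
                             group = gen_config$profile,
                             art_start_date = p$art_date,
                             stringsAsFactors = FALSE)
    mhc[[pids[i]]] <- p$mhc
    truth$participants[[pids[i]]] <-
      list(dominant = p$dominant, n_active = p$n_active[take],
           n_samples = p$n_samp)
    if (gen_config$profile == "plhiv") {
      clin[[i]] <- with_seed(derive_seed(gen_config$seed, hash_id(pids[i]), 2), {
        dates <- p$dates[take]
        yrs <- as.numeric(dates - p$art_date) / 365.25
        pre <- yrs < 0
        vl_log <- ifelse(pre,
                         runif(length(dates), clin_config$pre_art_viral_load[1],
                               clin_config$pre_art_viral_load[2]),
                         clin_config$post_art_viral_load) +
          rnorm(length(dates), 0, clin_config$vl_noise_sd)
        cd4 <- ifelse(pre, clin_config$cd4_start,
                      clin_config$cd4_plateau -
                        (clin_config$cd4_plateau - clin_config$cd4_start) *
                        exp(-clin_config$cd4_recovery_rate * pmax(yrs, 0))) +
          rnorm(length(dates), 0, clin_config$noise_sd)
        data.frame(participant_id = pids[i], date = dates,
                   viral_load = round(pmax(10^vl_log, 0)),
                   cd4_count = round(pmax(cd4, 10)),
                   stringsAsFactors = FALSE)
      })
    }
  }
  out <- cohort(reps, do.call(rbind, parts), mhc = mhc,
                clinical = if (gen_config$profile == "plhiv")
                  do.call(rbind, clin) else NULL)
  out$truth <- truth
  out
}

#' Spike public clonotypes into a cohort
#'
#' Inserts each annotated record's CDR3 amino acid sequence, at a fixed
#' repertoire frequency, into every repertoire of the participants whose
#' MHC genotype carries the record's restricting allele (family/two-field
#' matching rule); all other participants are untouched. Used for
#' closed-loop validation of the annotation and public-clonotype
#' detectors.
#'
#' @param x a `trb_cohort`.
#' @param records data.frame with columns `cdr3_aa` and `mhc_allele` (as
#'   returned by [read_annotation_db()]).
#' @param spike_freq target frequency of the spiked clone in each
#'   repertoire (template count `round(spike_freq * total_count)`, at
#'   least 1).
#' @param seed RNG seed for the synonymous back-translation of the spiked
#'   sequences.
#' @return the modified `trb_cohort`; the spike map is appended to
#'   `$truth$spikes`.
#' @export
spike_public_clonotypes <- function(x, records, spike_freq = 1e-3,
                                    seed = 1) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!nrow(records)) stop("records must be non-empty")
  stopifnot(all(c("cdr3_aa", "mhc_allele") %in% names(records)))
  bad <- !hla_parse(records$mhc_allele)$valid
  if (any(bad)) {
    stop("unparseable MHC allele in spike record: ",
         records$mhc_allele[which(bad)[1]])
  }
  st <- samples_table(x)
  spikes <- vector("list", nrow(records))
  for (r in seq_len(nrow(records))) {
    aa <- toupper(records$cdr3_aa[r])
    carriers <- names(x$mhc)[vapply(x$mhc, function(g)
      hla_match(records$mhc_allele[r], g), TRUE)]
    nt <- with_seed(derive_seed(seed, r, 7), back_translate(aa))
    for (sid in st$sample_id[st$participant_id %in% carriers]) {
      rep_i <- x$repertoires[[sid]]
      cnt <- max(1, round(spike_freq * total_count(rep_i)))
      rr <- rbind(rep_i$rearrangements,
                  data.frame(cdr3_nt = nt, cdr3_aa = aa,
                             v_gene = "TRBV19", j_gene = "TRBJ2-1",
                             productive = TRUE, count = cnt,
                             stringsAsFactors = FALSE))
      rep_i$rearrangements <- aggregate_rearrangements(rr)
      x$repertoires[[sid]] <- rep_i
    }
    spikes[[r]] <- list(cdr3_aa = aa,
                        mhc_allele = records$mhc_allele[r],
                        carriers = carriers)
  }
  if (is.null(x$truth)) x$truth <- list()
  x$truth$spikes <- c(x$truth$spikes, spikes)
  x
}
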