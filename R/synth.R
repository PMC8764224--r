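#' Specify intervention effects for the synthetic generator
#'
#' Describes the group-by-time effects (log2 scale) injected into a simulated
#' study. Two modes are supported. With `delta` given, the matrix is used as
#' is. Otherwise effects are realised stochastically: a fraction
#' `frac_affected` of features receive VLCD and RYGB effects drawn from a
#' bivariate normal with correlation `congruence_rho` and standard deviation
#' `effect_sd`, multiplied by a per-feature sign that is common to both arms
#' (a common sign leaves the correlation between the two effect vectors
#' unchanged). GOP effects are zero except for features listed in
#' `gop_effect_features`, mirroring a hormone infusion that leaves the
#' metabolome largely untouched; SAL effects are zero apart from an optional
#' common drift shared by all arms.
#'
#' The effect realisation uses its own fixed seed (`effect_seed`), separate
#' from the measurement-noise seed of [simulate_study()], so that studies
#' simulated with different noise seeds share identical ground-truth effects.
#'
#' @param delta optional numeric matrix (features x 4 columns named
#'   SAL/GOP/VLCD/RYGB) of log2 group-by-time effects.
#' @param congruence_rho target correlation between the VLCD and RYGB effect
#'   vectors, in `[-1, 1]`.
#' @param frac_affected proportion of features with a nonzero VLCD/RYGB
#'   effect, in `[0, 1]`.
#' @param effect_sd standard deviation (log2 units) of the bivariate-normal
#'   effect magnitudes.
#' @param gop_effect_features character vector of feature ids given a GOP
#'   effect (log2 magnitude `gop_effect_size`); empty by default.
#' @param gop_effect_size log2 effect for `gop_effect_features`.
#' @param sal_drift_sd SD of a per-feature time drift added to every arm
#'   (cancels in between-arm contrasts).
#' @param effect_seed integer seed for the effect realisation.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(delta = NULL, congruence_rho = 0.9, frac_affected = 1 / 3,
                        effect_sd = 0.75, gop_effect_features = character(),
                        gop_effect_size = 0.5, sal_drift_sd = 0,
                        effect_seed = 20210830L) {
  stopifnot(congruence_rho >= -1, congruence_rho <= 1,
            frac_affected >= 0, frac_affected <= 1,
            effect_sd >= 0, sal_drift_sd >= 0)
  if (!is.null(delta)) {
    delta <- as.matrix(delta)
    if (is.null(colnames(delta))) colnames(delta) <- study_groups()
    stopifnot(setequal(colnames(delta), study_groups()))
    delta <- delta[, study_groups(), drop = FALSE]
  }
  structure(list(delta = delta, congruence_rho = congruence_rho,
                 frac_affected = frac_affected, effect_sd = effect_sd,
                 gop_effect_features = gop_effect_features,
                 gop_effect_size = gop_effect_size,
                 sal_drift_sd = sal_drift_sd,
                 effect_seed = as.integer(effect_seed)),
            class = "effect_spec")
}

#' Specify noise components for the synthetic generator
#'
#' @param sigma_subject SD of the subject random intercept (log2 scale).
#' @param sigma_resid residual SD (log2 scale).
#' @param baseline_mu_range range of per-feature mean log2 intensities.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_subject = 0.5, sigma_resid = 0.3,
                       baseline_mu_range = c(10, 20)) {
  stopifnot(sigma_subject >= 0, sigma_resid >= 0,
            length(baseline_mu_range) == 2L,
            baseline_mu_range[1L] <= baseline_mu_range[2L])
  structure(list(sigma_subject = sigma_subject, sigma_resid = sigma_resid,
                 baseline_mu_range = baseline_mu_range),
            class = "noise_spec")
}

default_group_sizes <- function() c(SAL = 11L, GOP = 14L, VLCD = 22L, RYGB = 21L)

#' Deterministic synthetic feature annotation table
#'
#' Builds a feature table cycling through a realistic mix of metabolite
#' classes, with parseable lipid shorthand names for the lipid classes (chain
#' lengths and saturations cycle over small grids; fatty acids,
#' acylcarnitines, ceramides and sphingomyelins include very-long-chain
#' C24/C26 species, while phospholipid and lysophospholipid chains stop at
#' C22, mirroring typical preannotated panel composition), amino acids
#' including the branched-chain trio and
#' tyrosine, caffeine metabolites, TMAO, ketones and TCA intermediates. The
#' table is deterministic in `n_features`.
#'
#' @param n_features number of features.
#' @param platforms platform labels cycled over features.
#' @return data.frame with columns `feature_id`, `platform`,
#'   `metabolite_class`, `lipid_name`, `annotated`.
#' @export
synthetic_feature_table <- function(n_features,
                                    platforms = c("lipidRPCpos", "lipidRPCneg",
                                                  "HILICpos")) {
  carbons <- c(14L, 16L, 18L, 20L, 22L, 24L, 26L)
  dbs <- c(0L, 1L, 2L, 4L)
  chain <- function(i, max_carbons = 26L) {
    cc <- carbons[carbons <= max_carbons]
    c(cc[(i - 1L) %% length(cc) + 1L],
      dbs[(i - 1L) %/% length(cc) %% length(dbs) + 1L])
  }
  specials <- data.frame(
    metabolite_class = c("amino acid", "amino acid", "amino acid", "amino acid",
                         "BCAA", "BCAA", "BCAA", "tyrosine",
                         "caffeine metabolite", "caffeine metabolite", "TMAO",
                         "ketone", "ketone", "TCA intermediate", "TCA intermediate"),
    lipid_name = NA_character_
  )
  lipid_cycle <- c("fatty acid", "acylcarnitine", "triacylglycerol",
                   "phosphatidylcholine", "lysophospholipid", "ceramide",
                   "sphingomyelin", "other")
  rows <- vector("list", n_features)
  for (i in seq_len(n_features)) {
    if (i <= nrow(specials)) {
      rows[[i]] <- specials[i, ]
      next
    }
    cls <- lipid_cycle[(i - 1L) %% length(lipid_cycle) + 1L]
    blk <- 1L + (i - 1L) %/% length(lipid_cycle)
    cd <- chain(blk)
    ch <- paste0(cd[1L], ":", cd[2L])
    # phospholipid / lysophospholipid panels carry no very-long chains
    cd22 <- chain(blk, max_carbons = 22L)
    ch22 <- paste0(cd22[1L], ":", cd22[2L])
    nm <- switch(cls,
      "fatty acid" = paste0("FA(", ch, ")"),
      "acylcarnitine" = paste0("CAR(", ch, ")"),
      "triacylglycerol" = paste0("TG(", cd[1L] + 34L, ":", cd[2L], ")"),
      "phosphatidylcholine" = paste0("PC(16:0/", ch22, ")"),
      "lysophospholipid" = paste0(c("LPC", "LPE", "LPI")[i %% 3L + 1L],
                                  "(", ch22, ")"),
      "ceramide" = paste0("Cer(d18:1/", ch, ")"),
      "sphingomyelin" = paste0("SM(d18:1/", ch, ")"),
      NA_character_)
    rows[[i]] <- data.frame(metabolite_class = cls, lipid_name = nm)
  }
  out <- do.call(rbind, rows)
  data.frame(
    feature_id = sprintf("feat_%04d", seq_len(n_features)),
    platform = platforms[(seq_len(n_features) - 1L) %% length(platforms) + 1L],
    metabolite_class = out$metabolite_class,
    lipid_name = out$lipid_name,
    annotated = out$metabolite_class != "other",
    stringsAsFactors = FALSE
  )
}

#' Caloric-restriction effect template
#'
#' Assigns signed VLCD/RYGB effect directions by metabolite class, encoding
#' the lipidomic signature of an energetic switch to beta oxidation:
#' acylglycerols down, free fatty acids and acylcarnitines up, phospholipids
#' and lysophospholipids down, ketones and TCA-cycle intermediates up, with
#' very-long-chain (>= C24) fatty species sign-flipped to down. RYGB
#' additionally lowers branched-chain amino acids, tyrosine and caffeine
#' metabolites and raises TMAO, while VLCD leaves those near zero.
#'
#' Magnitudes are deterministic: for lipids with a parsed descriptor the
#' magnitude is keyed on the terminal acyl chain (carbons + double bonds),
#' so species sharing an acyl chain — a free fatty acid and the
#' phosphatidylcholines, lysophospholipids or acylcarnitines it matches —
#' respond with a common magnitude, mirroring chain-specific mobilization;
#' other features cycle over `magnitudes` in table order.
#'
#' @param features feature annotation data.frame as in [metabo_study()].
#' @param magnitudes positive log2 magnitudes cycled over affected features.
#' @param congruence_rho,effect_sd,... passed through to [effect_spec()]
#'   metadata (the returned spec carries an explicit `delta`, so these only
#'   annotate it).
#' @return An `effect_spec` with an explicit `delta` matrix.
#' @export
caloric_restriction_template <- function(features, magnitudes = c(0.5, 1.0), ...) {
  features <- as.data.frame(features)
  n <- nrow(features)
  delta <- matrix(0, n, 4L, dimnames = list(features$feature_id, study_groups()))

  sign_tab <- c("triacylglycerol" = -1, "acylglycerol" = -1,
                "fatty acid" = +1, "acylcarnitine" = +1,
                "phosphatidylcholine" = -1, "phospholipid" = -1,
                "lysophospholipid" = -1,
                "ketone" = +1, "TCA intermediate" = +1)
  rygb_tab <- c("BCAA" = -1, "tyrosine" = -1, "caffeine metabolite" = -1,
                "TMAO" = +1)

  descr <- lapply(features$lipid_name, function(nm) {
    if (is.na(nm)) NULL else suppressWarnings(parse_lipid_name(nm))
  })
  very_long_chain <- function(i) {
    d <- descr[[i]]
    if (is.null(d) || !d$lipid_class %in% c("FA", "CAR")) return(FALSE)
    any(d$chains$carbons >= 24L)
  }
  chain_magnitude <- function(i) {
    d <- descr[[i]]
    if (is.null(d)) return(NA_real_)
    ch <- d$chains[nrow(d$chains), ]  # terminal (sn-2 / N-acyl / only) chain
    magnitudes[(ch$carbons + ch$double_bonds) %% length(magnitudes) + 1L]
  }

  k <- 0L
  for (i in seq_len(n)) {
    cls <- features$metabolite_class[i]
    s <- if (cls %in% names(sign_tab)) sign_tab[[cls]] else 0
    s_rygb_extra <- if (cls %in% names(rygb_tab)) rygb_tab[[cls]] else 0
    if (s != 0 && very_long_chain(i)) s <- -1
    if (s != 0 || s_rygb_extra != 0) {
      k <- k + 1L
      mag <- chain_magnitude(i)
      if (is.na(mag)) mag <- magnitudes[(k - 1L) %% length(magnitudes) + 1L]
      if (s != 0) {
        delta[i, "VLCD"] <- s * mag
        delta[i, "RYGB"] <- s * mag
      }
      if (s_rygb_extra != 0) delta[i, "RYGB"] <- delta[i, "RYGB"] + s_rygb_extra * mag
    }
  }
  effect_spec(delta = delta, ...)
}

realize_effects <- function(effect, feature_ids) {
  n <- length(feature_ids)
  if (!is.null(effect$delta)) {
    stopifnot(nrow(effect$delta) == n)
    delta <- effect$delta
    rownames(delta) <- feature_ids
  } else {
    rs <- .Random.seed_save()
    on.exit(.Random.seed_restore(rs), add = TRUE)
    set.seed(effect$effect_seed)
    delta <- matrix(0, n, 4L, dimnames = list(feature_ids, study_groups()))
    n_aff <- round(effect$frac_affected * n)
    if (n_aff > 0) {
      aff <- sort(sample.int(n, n_aff))
      rho <- effect$congruence_rho
      z1 <- stats::rnorm(n_aff)
      z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n_aff)
      s <- sample(c(-1, 1), n_aff, replace = TRUE)
      delta[aff, "VLCD"] <- s * effect$effect_sd * z1
      delta[aff, "RYGB"] <- s * effect$effect_sd * z2
    }
    if (length(effect$gop_effect_features)) {
      idx <- match(effect$gop_effect_features, feature_ids)
      if (anyNA(idx)) stop("gop_effect_features not all present")
      delta[idx, "GOP"] <- effect$gop_effect_size
    }
    if (effect$sal_drift_sd > 0) {
      drift <- stats::rnorm(n, 0, effect$sal_drift_sd)
      delta <- delta + drift  # recycles over columns: common to all arms
    }
  }
  delta
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(rs) {
  if (is.null(rs)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", rs, envir = globalenv())
  }
}

default_clinical_spec <- function() {
  list(
    means = rbind(
      delta_weight            = c(SAL = -2,   GOP = -4,   VLCD = -8,   RYGB = -10),
      delta_fasting_glucose   = c(SAL = -0.2, GOP = -2.0, VLCD = -1.0, RYGB = -1.2),
      delta_fasting_insulin   = c(SAL = -5,   GOP = -25,  VLCD = -30,  RYGB = -35),
      delta_triglycerides     = c(SAL = 0,    GOP = -0.1, VLCD = -0.4, RYGB = 0.2),
      delta_total_cholesterol = c(SAL = 0,    GOP = -0.2, VLCD = -0.5, RYGB = -0.3)
    ),
    sds = c(delta_weight = 2, delta_fasting_glucose = 0.5,
            delta_fasting_insulin = 10, delta_triglycerides = 0.3,
            delta_total_cholesterol = 0.4)
  )
}

#' Simulate a complete intervention study with known ground truth
#'
#' Generates paired baseline/week-4 intensities for four treatment arms under
#' a log2-scale random-intercept model: for sample `s` of subject `i` in group
#' `g`, `log2 y = mu_f + b_i + delta[f, g] * 1{week4} + eps`, with
#' `b_i ~ N(0, sigma_subject^2)` and `eps ~ N(0, sigma_resid^2)`; intensities
#' are `2^y`, hence strictly positive. Clinical baseline-to-week-4 deltas are
#' drawn per group from configurable means/SDs, and features listed in
#' `clinical_link` additionally receive `slope * clinical_delta` on their
#' week-4 log2 values, tying them to a clinical factor.
#'
#' @param n_per_group named integer vector of arm sizes; defaults to
#'   SAL 11, GOP 14, VLCD 22, RYGB 21.
#' @param n_features number of features.
#' @param effect an [effect_spec()].
#' @param noise a [noise_spec()].
#' @param clinical_link optional data.frame with columns `feature_id`,
#'   `factor` (a clinical delta column name) and `slope`.
#' @param seed integer seed for noise and clinical draws (ground-truth
#'   effects use the effect specification's own `effect_seed`).
#' @param features optional feature annotation table; defaults to
#'   [synthetic_feature_table()].
#' @param clinical_spec list with per-factor group `means` matrix and `sds`;
#'   see the package defaults.
#' @param biofluid biofluid label for the generated samples.
#' @param n_missing_week4 number of subjects whose week-4 sample is dropped
#'   (to exercise unbalanced designs).
#' @return list with `study` (a [metabo_study()]) and `truth` (list with the
#'   full `delta` matrix, the realised VLCD-RYGB effect correlation over
#'   affected features, the affected feature ids, and the clinical links).
#' @export
simulate_study <- function(n_per_group = default_group_sizes(),
                           n_features = 500L,
                           effect = effect_spec(),
                           noise = noise_spec(),
                           clinical_link = NULL,
                           seed = 1L,
                           features = NULL,
                           clinical_spec = default_clinical_spec(),
                           biofluid = "plasma",
                           n_missing_week4 = 0L) {
  if (any(n_per_group < 1L)) stop("group sizes must be positive")
  if (any(n_per_group == 1L)) {
    warning("a group of size 1 cannot separate subject and residual variance")
  }
  stopifnot(setequal(names(n_per_group), study_groups()))
  n_per_group <- n_per_group[study_groups()]

  if (is.null(features)) features <- synthetic_feature_table(n_features)
  stopifnot(nrow(features) == n_features)
  delta <- realize_effects(effect, features$feature_id)

  groups <- rep(study_groups(), times = n_per_group)
  n_subj <- length(groups)
  subject_id <- sprintf("%s_%02d", groups,
                        unlist(lapply(n_per_group, seq_len), use.names = FALSE))

  set.seed(seed)
  b <- stats::rnorm(n_subj, 0, noise$sigma_subject)
  mu <- stats::runif(n_features, noise$baseline_mu_range[1L],
                     noise$baseline_mu_range[2L])

  cs <- clinical_spec
  clin <- data.frame(subject_id = subject_id)
  for (f in rownames(cs$means)) {
    clin[[f]] <- cs$means[f, groups] + stats::rnorm(n_subj, 0, cs$sds[[f]])
  }

  # log2 intensity matrix: 2 rows (baseline, week4) per subject
  y_base <- matrix(mu, n_subj, n_features, byrow = TRUE) + b +
    matrix(stats::rnorm(n_subj * n_features, 0, noise$sigma_resid),
           n_subj, n_features)
  y_wk4 <- matrix(mu, n_subj, n_features, byrow = TRUE) + b +
    t(delta[, groups, drop = FALSE]) +
    matrix(stats::rnorm(n_subj * n_features, 0, noise$sigma_resid),
           n_subj, n_features)

  if (!is.null(clinical_link)) {
    clinical_link <- as.data.frame(clinical_link)
    stopifnot(all(c("feature_id", "factor", "slope") %in% names(clinical_link)))
    for (k in seq_len(nrow(clinical_link))) {
      j <- match(clinical_link$feature_id[k], features$feature_id)
      if (is.na(j)) stop("clinical_link feature not present: ",
                         clinical_link$feature_id[k])
      fac <- clinical_link$factor[k]
      if (!fac %in% names(clin)) stop("unknown clinical factor: ", fac)
      y_wk4[, j] <- y_wk4[, j] + clinical_link$slope[k] * clin[[fac]]
    }
  }

  keep_wk4 <- rep(TRUE, n_subj)
  if (n_missing_week4 > 0L) {
    keep_wk4[sample.int(n_subj, n_missing_week4)] <- FALSE
  }

  samples <- data.frame(
    sample_id = c(paste0(subject_id, "_baseline"),
                  paste0(subject_id, "_week4")[keep_wk4]),
    subject_id = c(subject_id, subject_id[keep_wk4]),
    group = c(groups, groups[keep_wk4]),
    timepoint = c(rep("baseline", n_subj), rep("week4", sum(keep_wk4))),
    biofluid = biofluid,
    stringsAsFactors = FALSE
  )
  values <- 2^rbind(y_base, y_wk4[keep_wk4, , drop = FALSE])

  study <- metabo_study(values, samples, features, clinical = clin)

  affected <- features$feature_id[delta[, "VLCD"] != 0 | delta[, "RYGB"] != 0]
  realized_rho <- if (length(affected) >= 3L &&
                      stats::sd(delta[affected, "VLCD"]) > 0 &&
                      stats::sd(delta[affected, "RYGB"]) > 0) {
    stats::cor(delta[affected, "VLCD"], delta[affected, "RYGB"])
  } else NA_real_

  list(study = study,
       truth = list(delta = delta, realized_rho = realized_rho,
                    affected = affected, clinical_link = clinical_link))
}
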