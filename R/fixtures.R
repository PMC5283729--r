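#' Simulate a metabolomic intensity dataset with known truth
#'
#' Seeded generator emulating a GC-TOF-style untargeted experiment: features
#' have log-normal intensities (base log-means uniform over ~1e4-1e6), a
#' fraction of features carry a group effect of `effect_size` residual
#' standard deviations on the log scale, paired designs share a
#' subject-level random effect, and the instrument run is laid out as an
#' injection sequence with pooled QC samples every `qc_interval` injections.
#' Optional multiplicative signal drift over injection order (default
#' amplitude 30% across a batch) and feature-specific batch offsets make the
#' QC-LOESS correction testable against known truth.
#'
#' Supported designs: `two_independent`, `two_paired`, `multi_independent`,
#' `multi_paired`. Factorial layouts are better simulated directly at the
#' vector level for the factorial tests.
#'
#' @param n_features number of features.
#' @param design a [DesignSpec-class]; default paired two-group with factor
#'   `"group"` and subject column `"subject"`.
#' @param n_per_group biological samples per group (subjects, for paired
#'   designs).
#' @param n_groups group count for multi-group designs (default 3).
#' @param effect_frac fraction of features carrying a true effect.
#' @param effect_size effect magnitude in units of the residual log-scale SD
#'   (Cohen's d per observation).
#' @param sigma_e residual log-scale SD (default 0.5).
#' @param sigma_subject subject random-effect SD for paired designs.
#' @param n_batches number of instrument batches.
#' @param batch_sd log-scale SD of feature-specific batch offsets.
#' @param drift `"none"`, `"linear"` or `"smooth"` intensity drift over
#'   injection order.
#' @param drift_amplitude relative drift amplitude across a batch
#'   (default 0.3 = 30%).
#' @param qc_interval a QC sample is injected every this many injections.
#' @param qc_cv technical coefficient of variation of QC intensities
#'   (default 0.03).
#' @param missing_rate fraction of biological cells set missing at random.
#' @param seed integer seed (mandatory; the generator is deterministic
#'   given the seed).
#' @return list with `dataset` (a [MetaboSet-class]), `truth` (data.frame:
#'   `feature`, `is_effect`, `effect_log`), `design` (the
#'   [DesignSpec-class] used).
#' @export
simulateIntensityDataset <- function(n_features = 200,
                                     design = NULL,
                                     n_per_group = 20, n_groups = 3,
                                     effect_frac = 0.1, effect_size = 1,
                                     sigma_e = 0.5, sigma_subject = 0.5,
                                     n_batches = 1, batch_sd = 0.2,
                                     drift = c("none", "linear", "smooth"),
                                     drift_amplitude = 0.3,
                                     qc_interval = 10, qc_cv = 0.03,
                                     missing_rate = 0, seed) {
  .assert(!missing(seed), "a seed is mandatory")
  drift <- match.arg(drift)
  design <- design %||% designSpec("two_paired", "group", subject = "subject")
  .assert(design@design %in% c("two_independent", "two_paired",
                               "multi_independent", "multi_paired"),
          "generator supports one-factor designs only")
  .assert(effect_frac >= 0 && effect_frac <= 1, "effect_frac in [0,1]")
  paired <- design@design %in% c("two_paired", "multi_paired")
  k <- if (grepl("^two_", design@design)) 2L else as.integer(n_groups)
  fac_name <- design@factors[1L]

  .with_seed(seed, {
    groups <- paste0("g", seq_len(k))
    if (paired) {
      subj <- rep(seq_len(n_per_group), each = k)
      grp <- rep(groups, times = n_per_group)
      sid <- sprintf("s%02d_%s", subj, grp)
    } else {
      subj <- NULL
      grp <- rep(groups, each = n_per_group)
      sid <- sprintf("%s_r%02d", grp, rep(seq_len(n_per_group), times = k))
    }
    nbio <- length(sid)

    mu <- runif(n_features, log(1e4), log(1e6))
    n_eff <- round(effect_frac * n_features)
    is_eff <- rep(FALSE, n_features); is_eff[seq_len(n_eff)] <- TRUE
    delta <- ifelse(is_eff, effect_size * sigma_e, 0)

    logm <- matrix(mu, n_features, nbio)
    # effect on the last group level
    in_last <- grp == groups[k]
    logm[, in_last] <- logm[, in_last] + delta
    if (paired) {
      se <- matrix(rnorm(n_features * n_per_group, 0, sigma_subject),
                   n_features, n_per_group)
      logm <- logm + se[, subj, drop = FALSE]
    }
    logm <- logm + matrix(rnorm(n_features * nbio, 0, sigma_e), n_features, nbio)
    bio <- exp(logm)
    colnames(bio) <- sid; rownames(bio) <- sprintf("f%04d", seq_len(n_features))

    # instrument layout: randomized run order, QC every qc_interval injections
    batch_of <- sort(rep(seq_len(n_batches), length.out = nbio))
    cols <- list(); meta <- list()
    qc_sd <- sqrt(log(1 + qc_cv^2))
    bio_perm <- sample.int(nbio)  # run order of biological samples
    for (b in seq_len(n_batches)) {
      idx <- bio_perm[batch_of == b]
      nb <- length(idx)
      nqc <- max(4L, ceiling(nb / (qc_interval - 1)) + 1L)
      total <- nb + nqc
      qc_pos <- unique(round(seq(1, total, length.out = nqc)))
      bio_pos <- setdiff(seq_len(total), qc_pos)
      g <- switch(drift,
                  none = rep(1, total),
                  linear = 1 + drift_amplitude * (seq_len(total) - 1) / (total - 1),
                  smooth = 1 + drift_amplitude * sin(pi * (seq_len(total) - 1) / (total - 1)))
      boff <- if (n_batches > 1) exp(rnorm(n_features, 0, batch_sd)) else rep(1, n_features)
      bi <- 0L
      for (t in seq_len(total)) {
        if (t %in% qc_pos) {
          v <- exp(mu + rnorm(n_features, 0, qc_sd)) * g[t] * boff
          meta[[length(meta) + 1L]] <- data.frame(
            id = sprintf("QC_b%d_%03d", b, t), group = NA_character_,
            subject = NA_character_, batch = paste0("b", b),
            injection_order = t, sample_type = "qc", stringsAsFactors = FALSE)
        } else {
          bi <- bi + 1L
          j <- idx[bi]
          v <- bio[, j] * g[t] * boff
          meta[[length(meta) + 1L]] <- data.frame(
            id = sid[j], group = grp[j],
            subject = if (paired) paste0("sub", subj[j]) else NA_character_,
            batch = paste0("b", b), injection_order = t,
            sample_type = "biological", stringsAsFactors = FALSE)
        }
        cols[[length(cols) + 1L]] <- v
      }
    }
    mfull <- do.call(cbind, cols)
    md <- do.call(rbind, meta)
    colnames(mfull) <- md$id
    rownames(mfull) <- rownames(bio)
    if (missing_rate > 0) {
      mask <- matrix(runif(length(mfull)) < missing_rate, nrow(mfull))
      mask[, md$sample_type != "biological"] <- FALSE
      mfull[mask] <- NA
    }
    sm <- md[, -1L, drop = FALSE]
    names(sm)[names(sm) == "group"] <- fac_name
    if (!is.na(design@subject)) names(sm)[names(sm) == "subject"] <- design@subject
    ds <- MetaboSet(mfull, sample_meta = sm)
    truth <- data.frame(feature = rownames(bio), is_effect = is_eff,
                        effect_log = delta, stringsAsFactors = FALSE)
    list(dataset = ds, truth = truth, design = design)
  })
}

#' Draw p-values from a beta-uniform mixture
#'
#' With probability `lambda` a value is uniform on (0, 1); otherwise it is
#' Beta(a, 1) distributed (density a * p^(a-1), concentrating near 0).
#' Supports parameter-recovery testing of [fitBum()].
#'
#' @param lambda uniform-component weight in \[0, 1\].
#' @param a beta shape in (0, 1\]; `a = 1` is indistinguishable from uniform.
#' @param n number of draws.
#' @param seed integer seed.
#' @return numeric vector of p-values in (0, 1).
#' @export
simulatePvalues <- function(lambda, a, n, seed) {
  .assert(lambda >= 0 && lambda <= 1, "lambda in [0,1]")
  .assert(a > 0 && a <= 1, "a in (0,1]")
  .with_seed(seed, {
    unif <- runif(n) < lambda
    p <- numeric(n)
    p[unif] <- runif(sum(unif))
    p[!unif] <- rbeta(sum(!unif), a, 1)
    pmin(pmax(p, .Machine$double.eps), 1 - 1e-16)
  })
}

#' A small schema-valid knowledge graph for examples and tests
#'
#' 12 nodes and 15 edges covering every relation type: two genes encode
#' proteins (CONVERSION) that catalyse compound reactions (CATALYSIS,
#' BIOCHEMICAL_REACTION), proteins interact (MOLECULAR_BINDING), a protein
#' and a microRNA regulate genes (CONTROL), genes are associated
#' (GENETIC_ASSOCIATION), and one pathway annotates three compounds
#' (ANNOTATION); a second pathway has no annotations.
#'
#' @return a validated [KnowledgeGraph-class].
#' @export
toyKnowledgeGraph <- function() {
  nodes <- data.frame(
    id = c("g1", "g2", "p1", "p2", "p3", "c1", "c2", "c3", "c4",
           "mir1", "pw1", "pw2"),
    node_type = c("gene", "gene", "protein", "protein", "protein",
                  "compound", "compound", "compound", "compound",
                  "microRNA", "pathway", "pathway"),
    name = c("geneA", "geneB", "enzymeA", "enzymeB", "regulatorC",
             "cmpd1", "cmpd2", "cmpd3", "cmpd4", "miR-1",
             "pathway1", "pathway2"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    source = c("g1", "g2", "p1", "p1", "p2", "c1", "c2", "p1", "p2",
               "p3", "mir1", "g1", "pw1", "pw1", "pw1"),
    target = c("p1", "p2", "c1", "c2", "c3", "c2", "c3", "p2", "p3",
               "g1", "g2", "g2", "c1", "c2", "c3"),
    relation_type = c("CONVERSION", "CONVERSION", "CATALYSIS", "CATALYSIS",
                      "CATALYSIS", "BIOCHEMICAL_REACTION",
                      "BIOCHEMICAL_REACTION", "MOLECULAR_BINDING",
                      "MOLECULAR_BINDING", "CONTROL", "CONTROL",
                      "GENETIC_ASSOCIATION", "ANNOTATION", "ANNOTATION",
                      "ANNOTATION"),
    stringsAsFactors = FALSE)
  knowledgeGraph(nodes, edges)
}

#' Random substructure fingerprints
#'
#' Independent Bernoulli bits at the given density; a fingerprint that comes
#' out all-zero gets one random bit set so every fingerprint is usable.
#'
#' @param n number of fingerprints.
#' @param length bit-space length (default 881).
#' @param density per-bit set probability in (0, 1).
#' @param seed integer seed.
#' @return named list of fingerprints (ids `fp1`, `fp2`, ...).
#' @export
randomFingerprints <- function(n, length = 881, density = 0.1, seed) {
  .assert(density > 0 && density < 1, "density must be in (0, 1)")
  .with_seed(seed, {
    fps <- lapply(seq_len(n), function(i) {
      bits <- which(runif(length) < density) - 1L
      if (!length(bits)) bits <- sample.int(length, 1L) - 1L
      fingerprint(sprintf("fp%d", i), bits, length = length)
    })
    names(fps) <- sprintf("fp%d", seq_len(n))
    fps
  })
}
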