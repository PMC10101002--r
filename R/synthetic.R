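#' Default configuration of the synthetic-data generator
#'
#' The defaults emulate a two-workshop solid-state fermentation survey:
#' 2 groups x 6 time points (days 0, 2, 5, 10, 15, 30) x 4 replicates =
#' 48 samples; 400 bacterial and 200 fungal taxa sequenced at mean depths
#' of 40,000 and 43,000 reads; a lognormal metacommunity (sdlog = 2)
#' sampled under Sloan neutral dynamics with migration rate `m_true =
#' 0.1`; a subset of selected taxa responding log-linearly to the
#' temperature trajectory; five planted correlation blocks (three
#' bacterial, two fungal) driven by per-module lognormal latent factors;
#' connector taxa loading on the three mutually correlated bacterial
#' module factors (a node can only reach participation >= 0.62 by linking
#' at least three modules, and correlation >= 0.8 with several factors
#' requires those factors to be correlated themselves); and metabolites
#' generated as linear functions of module 0's Shannon diversity
#' (ethyl acetate negatively, the three higher-alcohol components
#' positively) with noise calibrated to a target correlation of 0.7.
#'
#' @param ... named overrides of any default.
#' @return a list of class `generator_config`.
#' @export
default_generator_config <- function(...) {
  cfg <- list(
    groups = c("A", "B"),
    days = c(0, 2, 5, 10, 15, 30),
    replicates = 4,
    n_bact = 400, n_fungi = 200,
    depth_bact = 40000, depth_fungi = 43000,
    m_true = 0.1,
    sigma_log = 2,              # lognormal metacommunity spread
    n_selected = 20,            # temperature-responding taxa (bacterial)
    selected_beta_sd = 1,       # log-abundance response per sd of temperature
    module_sizes = c(14, 13, 12, 11, 10),  # modules 0-2 bacterial, 3-4 fungal
    n_bact_modules = 3,
    n_connectors = 3,
    factor_sd = 1.0,            # sigma of the shared per-module log factor
    taxon_noise_sd = 0.2,       # independent per-taxon log noise in blocks
    trio_cor = 0.8,             # correlation among the bacterial module factors
    block_mass = 0.06,          # metacommunity mass of block taxa per domain
    selected_mass = 0.05,
    n_noise_metabolites = 30,
    ea_slope = -1.5,            # ethyl acetate ~ module-0 SDI
    ha_slope = 2.0,             # summed higher alcohols ~ module-0 SDI
    target_r = 0.7,             # |correlation| of coupled metabolites with SDI
    linked_module = "0"
  )
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "generator_config"
  cfg
}

#' Generate a synthetic paired fermentation dataset with planted truth
#'
#' Produces bacterial and fungal count tables, a metabolite table, sample
#' metadata, and a `truth` record of every planted structure, so that each
#' pipeline stage can be scored against known ground truth. See
#' [default_generator_config()] for what is planted. Identical seeds give
#' byte-identical datasets.
#'
#' @param config a [default_generator_config()] (or one with overrides).
#' @param seed integer RNG seed.
#' @return list with `bacteria`, `fungi` ([abundance_table()]s of counts),
#'   `metabolites` ([metabolite_table()]), `metadata` (data.frame), and
#'   `truth` (list: `meta_p`, `m_true`, `module_assignment`, `connectors`,
#'   `selected`, `metabolite_model`, `config`, `seed`).
#' @export
generate_dataset <- function(config = default_generator_config(), seed = 1) {
  cfg <- config
  n_modules <- length(cfg$module_sizes)
  if (cfg$n_bact_modules > n_modules) stop2("n_bact_modules exceeds module count")
  if (cfg$n_connectors > 0 && cfg$n_bact_modules < 3) {
    stop2("connectors need at least 3 (correlated) bacterial modules to reach Pi >= 0.62")
  }
  samples <- expand.grid(rep = seq_len(cfg$replicates), day = cfg$days,
                         group = cfg$groups, stringsAsFactors = FALSE)
  sample_id <- sprintf("%s_d%02d_r%d", samples$group, samples$day, samples$rep)
  ns <- nrow(samples)

  with_seed(seed, {
    # --- metadata: temperature trajectories differ by workshop after onset
    temp_mean <- ifelse(samples$group == "A",
                        20 + 12 * exp(-((samples$day - 12) / 10)^2),
                        20 + 8 * exp(-((samples$day - 8) / 10)^2))
    temperature <- temp_mean + stats::rnorm(ns, 0, 0.5)
    moisture <- 52 + 0.25 * samples$day + stats::rnorm(ns, 0, 1)
    acidity <- 1.2 + 0.07 * samples$day + stats::rnorm(ns, 0, 0.1)
    metadata <- data.frame(sample_id = sample_id, group = samples$group,
                           time = samples$day, temperature = temperature,
                           moisture = moisture, acidity = acidity,
                           stringsAsFactors = FALSE)
    rownames(metadata) <- sample_id

    # --- shared latent module factors (samples x modules)
    bact_mods <- seq_len(cfg$n_bact_modules)
    fung_mods <- setdiff(seq_len(n_modules), bact_mods)
    Fm <- matrix(stats::rnorm(ns * n_modules), ns, n_modules)
    # correlate the bacterial trio: F_b = sqrt(r) Z0 + sqrt(1-r) Z_b
    if (length(bact_mods) >= 2) {
      z0 <- stats::rnorm(ns)
      r <- cfg$trio_cor
      Fm[, bact_mods] <- sqrt(r) * z0 + sqrt(1 - r) * Fm[, bact_mods]
    }
    connector_load <- rowSums(Fm[, bact_mods, drop = FALSE])
    connector_load <- connector_load / stats::sd(connector_load)

    build_domain <- function(n_taxa, depth, module_ids, prefix, domain,
                             selected_here, connectors_here) {
      sizes <- cfg$module_sizes[module_ids]
      n_block <- sum(sizes)
      n_conn <- if (connectors_here) cfg$n_connectors else 0L
      n_sel <- if (selected_here) cfg$n_selected else 0L
      n_neutral <- n_taxa - n_block - n_conn - n_sel
      if (n_neutral < 10) stop2("config leaves too few neutral taxa in ", domain)
      ids <- sprintf("%s%04d", prefix, seq_len(n_taxa))
      kind <- rep("neutral", n_taxa)
      block_of <- rep(NA_character_, n_taxa)
      i <- n_neutral
      for (b in seq_along(module_ids)) {
        idx <- i + seq_len(sizes[b]); i <- i + sizes[b]
        kind[idx] <- "block"
        block_of[idx] <- as.character(module_ids[b] - 1L)  # 0-based labels
      }
      conn_idx <- sel_idx <- integer(0)
      if (n_conn) { conn_idx <- i + seq_len(n_conn); i <- i + n_conn; kind[conn_idx] <- "connector" }
      if (n_sel) { sel_idx <- i + seq_len(n_sel); kind[sel_idx] <- "selected" }

      # metacommunity abundances: lognormal within each compartment, with
      # fixed mass shares so the planted taxa are abundant enough to survive
      # prevalence filtering
      meta_p <- numeric(n_taxa)
      draw_mass <- function(k, mass) {
        v <- stats::rlnorm(k, 0, cfg$sigma_log)
        v / sum(v) * mass
      }
      mass_block <- if (n_block) cfg$block_mass else 0
      mass_sel <- if (n_sel) cfg$selected_mass else 0
      mass_conn <- if (n_conn) 0.02 else 0
      meta_p[kind == "neutral"] <- draw_mass(n_neutral, 1 - mass_block - mass_sel - mass_conn)
      if (n_block) {
        v <- stats::rlnorm(n_block, 0, 0.5)  # narrower: keep block taxa detectable
        meta_p[kind == "block"] <- v / sum(v) * mass_block
      }
      if (n_conn) meta_p[conn_idx] <- mass_conn / n_conn
      if (n_sel) {
        v <- stats::rlnorm(n_sel, 0, 1)
        meta_p[sel_idx] <- v / sum(v) * mass_sel
      }
      names(meta_p) <- ids

      # per-sample expected intensities
      intensity <- matrix(0, n_taxa, ns, dimnames = list(ids, sample_id))
      neu <- kind == "neutral"
      shape <- depth * cfg$m_true * meta_p[neu]
      for (j in seq_len(ns)) {
        g <- stats::rgamma(sum(neu), shape = shape)
        intensity[neu, j] <- g
      }
      # scale neutral intensities so the neutral compartment keeps its mass
      neu_mass <- sum(meta_p[neu])
      for (j in seq_len(ns)) {
        s <- sum(intensity[neu, j])
        if (s > 0) intensity[neu, j] <- intensity[neu, j] / s * neu_mass
      }
      for (tix in which(kind == "block")) {
        b <- match(as.character(as.integer(block_of[tix]) + 1L), as.character(module_ids))
        f <- Fm[, module_ids[b]]
        intensity[tix, ] <- meta_p[tix] *
          exp(cfg$factor_sd * f + cfg$taxon_noise_sd * stats::rnorm(ns))
      }
      for (tix in conn_idx) {
        intensity[tix, ] <- meta_p[tix] *
          exp(cfg$factor_sd * connector_load + (cfg$taxon_noise_sd / 2) * stats::rnorm(ns))
      }
      beta_sel <- numeric(0)
      if (n_sel) {
        beta_sel <- stats::rnorm(n_sel, 0, cfg$selected_beta_sd)
        env_z <- (temperature - mean(temperature)) / stats::sd(temperature)
        for (k in seq_len(n_sel)) {
          tix <- sel_idx[k]
          intensity[tix, ] <- meta_p[tix] *
            exp(beta_sel[k] * env_z + cfg$taxon_noise_sd * stats::rnorm(ns))
        }
        names(beta_sel) <- ids[sel_idx]
      }
      counts <- matrix(0L, n_taxa, ns, dimnames = dimnames(intensity))
      for (j in seq_len(ns)) {
        counts[, j] <- stats::rmultinom(1, depth, intensity[, j])[, 1]
      }
      list(table = abundance_table(counts, domain = domain, is_relative = FALSE),
           meta_p = meta_p, kind = kind, block_of = block_of,
           connectors = ids[conn_idx], selected_beta = beta_sel)
    }

    bact <- build_domain(cfg$n_bact, cfg$depth_bact, bact_mods, "b_otu",
                         "bacteria", selected_here = TRUE, connectors_here = TRUE)
    fung <- build_domain(cfg$n_fungi, cfg$depth_fungi, fung_mods, "f_otu",
                         "fungi", selected_here = FALSE, connectors_here = FALSE)

    module_assignment <- c(
      stats::setNames(bact$block_of[!is.na(bact$block_of)],
                      taxa_ids(bact$table)[!is.na(bact$block_of)]),
      stats::setNames(fung$block_of[!is.na(fung$block_of)],
                      taxa_ids(fung$table)[!is.na(fung$block_of)])
    )

    # --- metabolites coupled to module-0 Shannon diversity
    merged <- merge_domains(bact$table, fung$table, normalize = "domain")
    mod0 <- names(module_assignment)[module_assignment == cfg$linked_module]
    sdi0 <- vapply(sample_id, function(s) shannon_index(merged, s, mod0), numeric(1))
    sd_sdi <- stats::sd(sdi0)
    noise_for <- function(slope) {
      # sd giving |cor(metabolite, SDI)| ~ target_r
      abs(slope) * sd_sdi * sqrt(1 / cfg$target_r^2 - 1)
    }
    ha_each <- cfg$ha_slope / 3
    met_model <- data.frame(
      metabolite = c("ethyl_acetate", "isoamyl_alcohol", "phenethyl_alcohol",
                     "isobutanol"),
      module = cfg$linked_module,
      slope = c(cfg$ea_slope, ha_each, ha_each, ha_each),
      intercept = c(10, 5, 5, 5),
      noise_sd = c(noise_for(cfg$ea_slope), rep(noise_for(cfg$ha_slope) / sqrt(3), 3)),
      stringsAsFactors = FALSE
    )
    conc <- t(vapply(seq_len(nrow(met_model)), function(k) {
      pmax(met_model$intercept[k] + met_model$slope[k] * sdi0 +
             stats::rnorm(ns, 0, met_model$noise_sd[k]), 0)
    }, numeric(ns)))
    rownames(conc) <- met_model$metabolite
    noise_met <- matrix(stats::rlnorm(cfg$n_noise_metabolites * ns, 1, 0.5),
                        cfg$n_noise_metabolites, ns,
                        dimnames = list(sprintf("metab%02d",
                                                seq_len(cfg$n_noise_metabolites)),
                                        sample_id))
    colnames(conc) <- sample_id
    metabolites <- metabolite_table(rbind(conc, noise_met))

    truth <- list(
      meta_p = list(bacteria = bact$meta_p, fungi = fung$meta_p),
      m_true = cfg$m_true,
      module_assignment = module_assignment,
      connectors = bact$connectors,
      selected = bact$selected_beta,
      metabolite_model = met_model,
      sdi0 = sdi0,
      config = cfg,
      seed = seed
    )
    list(bacteria = bact$table, fungi = fung$table, metabolites = metabolites,
         metadata = metadata, truth = truth)
  })
}

#' Synthetic metabolite panel for indicator-selection validation
#'
#' Two groups differing only in a few informative metabolites: every
#' feature is N(10, 1) noise except `n_informative` features shifted by
#' `effect` standard deviations in group B. The default per-feature shift
#' of 1.5 sd gives a combined (Mahalanobis) group separation of about 3
#' sd over the four informative features, so that single features remain
#' imperfect classifiers and the cross-validation error keeps improving
#' until all informative features are included.
#'
#' @param n_per_group samples per group, default 36.
#' @param n_noise uninformative features, default 30.
#' @param n_informative shifted features, default 4.
#' @param effect per-feature shift in units of the noise sd, default 1.5.
#' @param seed RNG seed.
#' @return list with `metabolites` ([metabolite_table()]), `metadata`,
#'   and `informative` (feature IDs carrying signal).
#' @export
simulate_indicator_metabolites <- function(n_per_group = 36, n_noise = 30,
                                           n_informative = 4, effect = 1.5,
                                           seed = 1) {
  ns <- 2 * n_per_group
  p <- n_noise + n_informative
  ids <- c(sprintf("signal%02d", seq_len(n_informative)),
           sprintf("noise%02d", seq_len(n_noise)))
  sample_id <- sprintf("s%03d", seq_len(ns))
  group <- rep(c("A", "B"), each = n_per_group)
  X <- with_seed(seed, {
    m <- matrix(stats::rnorm(p * ns, 10, 1), p, ns,
                dimnames = list(ids, sample_id))
    m[seq_len(n_informative), group == "B"] <-
      m[seq_len(n_informative), group == "B"] + effect
    m
  })
  metadata <- data.frame(sample_id = sample_id, group = group,
                         stringsAsFactors = FALSE)
  rownames(metadata) <- sample_id
  list(metabolites = metabolite_table(pmax(X, 0)), metadata = metadata,
       informative = ids[seq_len(n_informative)])
}

#' Score pipeline outputs against planted ground truth
#'
#' Compares whatever results are supplied with the generator's `truth`
#' record: adjusted Rand index of a detected module partition against the
#' planted blocks (over taxa with a planted single-block label),
#' precision/recall of connector classification, enriched taxa, and
#' indicator metabolites, the migration-rate error, and metabolite slope
#' recovery errors.
#'
#' @param truth the `truth` element of [generate_dataset()].
#' @param results named list; recognized elements: `partition` (named
#'   module vector or a partitioned network), `roles` ([zi_pi()] result),
#'   `neutral` (`neutral_fit`), `enrichment` ([differential_enrichment()]
#'   result), `indicators` (`indicator_result`), `regression`
#'   ([diversity_metabolite_regression()] result).
#' @return named list of recovery metrics (only those computable).
#' @export
truth_report <- function(truth, results) {
  out <- list()
  pr <- function(found, planted) {
    tp <- length(intersect(found, planted))
    list(precision = if (length(found)) tp / length(found) else NA_real_,
         recall = if (length(planted)) tp / length(planted) else NA_real_)
  }
  if (!is.null(results$partition)) {
    part <- if (inherits(results$partition, "cooccurrence_network")) {
      results$partition$partition
    } else results$partition
    shared <- intersect(names(part), names(truth$module_assignment))
    if (!length(shared)) stop2("no taxa shared between partition and planted modules")
    out$module_ari <- adjusted_rand_index(part[shared],
                                          truth$module_assignment[shared])
  }
  if (!is.null(results$roles)) {
    found <- results$roles$taxon[results$roles$Pi >= 0.62]
    out$connector <- pr(found, truth$connectors)
  }
  if (!is.null(results$neutral)) {
    out$m_error <- results$neutral$m - truth$m_true
    out$m_relative_error <- out$m_error / truth$m_true
  }
  if (!is.null(results$enrichment)) {
    found <- results$enrichment$taxon[!is.na(results$enrichment$enriched_in)]
    out$enriched <- pr(found, names(truth$selected))
  }
  if (!is.null(results$indicators)) {
    planted <- if (!is.null(truth$informative)) truth$informative else
      truth$metabolite_model$metabolite
    out$indicator <- pr(results$indicators$selected, planted)
  }
  if (!is.null(results$regression)) {
    reg <- results$regression
    mm <- truth$metabolite_model
    err <- vapply(seq_len(nrow(mm)), function(k) {
      row <- reg[reg$metabolite == mm$metabolite[k] & reg$module == mm$module[k], ]
      if (!nrow(row)) return(NA_real_)
      row$slope[1] - mm$slope[k]
    }, numeric(1))
    names(err) <- mm$metabolite
    out$slope_error <- err
  }
  out
}
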