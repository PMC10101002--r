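#' Per-sample module diversity and abundance profiles
#'
#' For every module (ecological cluster) of a partitioned network and
#' every sample: the Shannon diversity index over the module's member
#' taxa (abundances renormalized within the module, nats) and the summed
#' relative abundance of the module, z-scored across samples.
#'
#' @param t an [abundance_table()] containing (at least) the network's taxa.
#' @param net a `cooccurrence_network` with a module partition, or a named
#'   vector/list mapping taxon -> module ID.
#' @param min_module_size skip modules smaller than this (default 1 keeps
#'   all).
#' @return object of class `module_profile`: list with `sdi` (modules x
#'   samples), `ra` (summed RA), `ra_z` (z-scored per module), `members`
#'   (list of taxon vectors).
#' @export
module_profiles <- function(t, net, min_module_size = 1L) {
  stopifnot(inherits(t, "abundance_table"))
  part <- if (inherits(net, "cooccurrence_network")) {
    if (is.null(net$partition)) stop2("run detect_modules() first")
    net$partition
  } else unlist(net)
  missing <- setdiff(names(part), taxa_ids(t))
  if (length(missing)) {
    stop2("network taxa absent from abundance table: ",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  ra <- to_relative(t)$counts
  mods <- sort(unique(part))
  members <- lapply(mods, function(m) names(part)[part == m])
  names(members) <- as.character(mods)
  members <- members[vapply(members, length, 1L) >= min_module_size]
  samples <- colnames(ra)
  sdi <- matrix(NA_real_, length(members), length(samples),
                dimnames = list(names(members), samples))
  ra_sum <- sdi
  for (m in names(members)) {
    sub <- ra[members[[m]], , drop = FALSE]
    tot <- colSums(sub)
    if (all(tot == 0)) warn2("module ", m, " has zero abundance in all samples")
    for (j in seq_along(samples)) {
      if (tot[j] == 0) { sdi[m, j] <- 0; next }
      p <- sub[, j][sub[, j] > 0] / tot[j]
      sdi[m, j] <- -sum(p * log(p))
    }
    ra_sum[m, ] <- tot
  }
  ra_z <- t(apply(ra_sum, 1, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  dimnames(ra_z) <- dimnames(ra_sum)
  structure(list(sdi = sdi, ra = ra_sum, ra_z = ra_z, members = members),
            class = "module_profile")
}

#' Regress metabolite concentrations on module diversity or abundance
#'
#' Ordinary least squares of each metabolite concentration on the chosen
#' per-sample module predictor (Shannon diversity or z-scored summed
#' relative abundance), over the samples shared by both tables; two-sided
#' slope p-values with BH adjustment across all (module, metabolite)
#' pairs. Constant predictors are skipped with a warning. If
#' `higher_alcohols` components are present in the metabolite table, their
#' per-sample sum is appended as a derived metabolite `"higher_alcohols"`.
#'
#' @param mp a [module_profiles()] result.
#' @param met a [metabolite_table()].
#' @param predictor `"SDI"` or `"RA_z"`.
#' @param higher_alcohols component metabolite IDs summed into the derived
#'   `higher_alcohols` response when all are present; default the three
#'   classic ones.
#' @return data.frame of class `module_regression`: per (module,
#'   metabolite) `slope`, `intercept`, `r`, `p`, `p_adj`, `n`.
#' @export
diversity_metabolite_regression <- function(mp, met, predictor = c("SDI", "RA_z"),
                                            higher_alcohols = c("isoamyl_alcohol",
                                                                "phenethyl_alcohol",
                                                                "isobutanol")) {
  predictor <- match.arg(predictor)
  stopifnot(inherits(mp, "module_profile"))
  X <- if (predictor == "SDI") mp$sdi else mp$ra_z
  met <- as.matrix(met)
  shared <- intersect(colnames(X), colnames(met))
  if (length(shared) < 4L) stop2("need at least 4 shared samples")
  X <- X[, shared, drop = FALSE]
  met <- met[, shared, drop = FALSE]
  if (all(higher_alcohols %in% rownames(met)) &&
      !"higher_alcohols" %in% rownames(met)) {
    met <- rbind(met, higher_alcohols = colSums(met[higher_alcohols, , drop = FALSE]))
  }
  rows <- list()
  for (m in rownames(X)) {
    x <- X[m, ]
    if (stats::sd(x) == 0) {
      warn2("constant predictor for module ", m, "; skipped")
      next
    }
    for (y_id in rownames(met)) {
      y <- met[y_id, ]
      fit <- stats::lm(y ~ x)
      sm <- summary(fit)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, metabolite = y_id,
        slope = unname(stats::coef(fit)[2L]),
        intercept = unname(stats::coef(fit)[1L]),
        slope_se = sm$coefficients[2L, 2L],
        r = unname(stats::cor(x, y)),
        p = sm$coefficients[2L, 4L],
        n = length(shared),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("module_regression", "data.frame")
  out
}
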