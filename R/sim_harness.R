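#' Query-point plan for effect evaluation
#'
#' Builds the set of exposure query points (original scale, pooled type-7
#' quantiles) and within-group contrasts used to evaluate a fitted model:
#' surface contrasts along per-exposure quantile grids (other exposures at
#' the median, relative to the all-median point), total-mixture contrasts of
#' all-exposures-at-q versus all-at-median, and single-exposure
#' interquartile contrasts at several conditioning quantiles. The degenerate
#' median-versus-median contrast is excluded.
#'
#' @param dataset A `mixture_data`.
#' @param qs Quantile grid (first to third quartile by default).
#' @param cond_q Conditioning quantiles for single-exposure contrasts.
#' @return A list with `points` (matrix of unique query points), `contrasts`
#'   (data.frame: `effect_type`, `key`, point indices `ia`, `ib`), and
#'   `pairs` (group pairs for between-group differences).
#' @export
build_effect_plan <- function(dataset, qs = seq(0.25, 0.75, by = 0.05),
                              cond_q = c(0.25, 0.5, 0.75)) {
  M <- dataset$M
  qvals <- vapply(qs, function(q) quantile_points(dataset, q), numeric(M))
  rownames(qvals) <- dataset$names$exposures
  qat <- function(q) qvals[, match(q, qs)]

  pts <- list()
  keyof <- function(p) paste(signif(p, 12), collapse = "|")
  add_point <- function(p) {
    k <- keyof(p)
    if (is.null(pts[[k]])) pts[[k]] <<- p
    k
  }
  med <- add_point(qat(0.5))

  contrasts <- list()
  add_contrast <- function(type, key, ka, kb) {
    contrasts[[length(contrasts) + 1L]] <<-
      data.frame(effect_type = type, key = key, ka = ka, kb = kb)
  }
  for (q in setdiff(qs, 0.5)) {
    # surface: one exposure moves along its grid, others at median
    for (m in seq_len(M)) {
      p <- qat(0.5); p[m] <- qvals[m, match(q, qs)]
      add_contrast("surface", sprintf("m%d|q%.2f", m, q), add_point(p), med)
    }
    # total mixture: all exposures move together
    add_contrast("group_total", sprintf("q%.2f", q), add_point(qat(q)), med)
  }
  for (m in seq_len(M)) {
    for (qc in cond_q) {
      pa <- qat(qc); pa[m] <- qvals[m, match(0.75, qs)]
      pb <- qat(qc); pb[m] <- qvals[m, match(0.25, qs)]
      add_contrast("group_single", sprintf("m%d|qc%.2f", m, qc),
                   add_point(pa), add_point(pb))
    }
  }
  keys <- names(pts)
  points <- do.call(rbind, pts)
  ct <- do.call(rbind, contrasts)
  ct$ia <- match(ct$ka, keys)
  ct$ib <- match(ct$kb, keys)
  ct$ka <- ct$kb <- NULL
  P <- dataset$P
  pairs <- if (P >= 2L) {
    cmb <- utils::combn(P, 2L)
    data.frame(g1 = cmb[1L, ], g2 = cmb[2L, ])
  } else {
    data.frame(g1 = integer(), g2 = integer())
  }
  list(points = points, contrasts = ct, pairs = pairs)
}

# Effect estimates (posterior mean + 95% CrI) for one fitted model over a
# plan, batching all query points into one conditional-sampling pass per
# posterior. `fitobj` is a kmr fit or a kmr_stratified object.
model_effect_estimates <- function(fitobj, model, dataset, plan) {
  Zq <- apply_standardization(plan$points, dataset$std)
  K <- nrow(Zq)
  P <- dataset$P
  ct <- plan$contrasts

  # per-group matrices of sampled h draws at the plan points
  h_by_group <- if (model == "stratified") {
    lapply(seq_len(P), function(g) {
      posterior_h_samples(fitobj$fits[[g]], Zq, rep.int(1L, K),
                          seed_key = K + g)
    })
  } else if (model == "exposure_only") {
    h <- posterior_h_samples(fitobj, Zq, rep.int(1L, K), seed_key = K)
    rep(list(h), P)  # single shared surface evaluated against each group
  } else {
    # joint fit: one conditional-sampling pass over all groups' copies of
    # the query points (one factorization per draw instead of P)
    wq <- rep(seq_len(P), each = K)
    H <- posterior_h_samples(fitobj, Zq[rep(seq_len(K), times = P), ,
                                        drop = FALSE],
                             wq, seed_key = K * P)
    lapply(seq_len(P), function(g) {
      H[, (g - 1L) * K + seq_len(K), drop = FALSE]
    })
  }

  summarize_draws <- function(D, type, group, key) {
    data.frame(effect_type = type, group = group, key = key,
               est = colMeans(D),
               lower = apply(D, 2L, stats::quantile, 0.025, type = 7),
               upper = apply(D, 2L, stats::quantile, 0.975, type = 7))
  }
  group_contrast_draws <- function(g) {
    h_by_group[[g]][, ct$ia, drop = FALSE] -
      h_by_group[[g]][, ct$ib, drop = FALSE]
  }
  D_g <- lapply(seq_len(P), group_contrast_draws)
  est <- do.call(rbind, lapply(seq_len(P), function(g) {
    summarize_draws(D_g[[g]], ct$effect_type, as.character(g), ct$key)
  }))
  if (model != "exposure_only" && nrow(plan$pairs)) {
    sub <- which(ct$effect_type %in% c("group_total", "group_single"))
    diffs <- do.call(rbind, lapply(seq_len(nrow(plan$pairs)), function(k) {
      g1 <- plan$pairs$g1[k]; g2 <- plan$pairs$g2[k]
      Dd <- D_g[[g1]][, sub, drop = FALSE] - D_g[[g2]][, sub, drop = FALSE]
      summarize_draws(Dd, sub("group", "diff", ct$effect_type[sub]),
                      paste0(g1, "-", g2), ct$key[sub])
    }))
    est <- rbind(est, diffs)
  }
  rownames(est) <- NULL
  est
}

#' Compare effect estimates with ground truth for one replicate
#'
#' Joins estimates and truths on (effect type, group, contrast key) and
#' computes, per effect type: RMSE of the posterior mean, 95% CrI coverage
#' (inclusive endpoints) and average CrI width, averaging over contrast
#' points and groups.
#'
#' @param estimates Data.frame from the harness with columns `effect_type`,
#'   `group`, `key`, `est`, `lower`, `upper`.
#' @param truth Data.frame with columns `effect_type`, `group`, `key`,
#'   `truth` (from [generate_dataset()]).
#' @return Data.frame with one row per effect type: `rmse`, `coverage`,
#'   `width`, `n_contrasts`.
#' @export
evaluate_fit <- function(estimates, truth) {
  m <- merge(estimates, truth, by = c("effect_type", "group", "key"))
  if (nrow(m) != nrow(estimates))
    stop("estimates and truth are misaligned: ",
         nrow(estimates) - nrow(m), " unmatched rows")
  agg <- lapply(split(m, m$effect_type), function(d) {
    data.frame(effect_type = d$effect_type[1L],
               rmse = sqrt(mean((d$est - d$truth)^2)),
               coverage = mean(d$lower <= d$truth & d$truth <= d$upper),
               width = mean(d$upper - d$lower),
               n_contrasts = nrow(d))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

kmr_models <- c("exposure_only", "modifier_in_kernel", "group_separable",
                "stratified")

fit_model <- function(model, dataset, priors, control) {
  switch(model,
    exposure_only = kmr(dataset, "standard", priors, control),
    modifier_in_kernel = kmr(dataset, "modifier_in_kernel", priors, control),
    group_separable = kmr(dataset, "group_separable", priors, control),
    stratified = kmr_stratified(dataset, priors, control),
    stop("unknown model '", model, "'; valid models: ",
         paste(kmr_models, collapse = ", "))
  )
}

#' Run a simulation scenario over replicated datasets
#'
#' For each replicate: generate a dataset from the scenario, fit each
#' requested model, compute group-specific and between-group effect
#' estimates on the quantile-grid plan, and score them against the ground
#' truth. Metrics are averaged over replicates with Monte-Carlo standard
#' errors. Failed replicates are recorded and skipped, never silent.
#'
#' @param spec A [scenario_spec()] (its `seed` field is ignored; per-replicate
#'   seeds derive from `master_seed`).
#' @param models Character vector of model ids among `"exposure_only"`,
#'   `"modifier_in_kernel"`, `"group_separable"`, `"stratified"`.
#' @param reps Number of replicated datasets.
#' @param priors,control Passed to the fitting functions.
#' @param master_seed Master seed; replicate r uses a seed derived from it.
#' @param scenario_id Label recorded in the output table.
#' @param checkpoint_dir Optional directory: per-replicate results are
#'   written there as CSV and reused when rerunning.
#' @param verbose Print per-replicate progress.
#' @return A data.frame of class `metrics_table` with columns `scenario`,
#'   `model`, `effect_type`, `rmse`, `coverage`, `width`, their Monte-Carlo
#'   standard errors, `reps` and `failures`.
#' @export
run_scenario <- function(spec, models = kmr_models, reps = 10,
                         priors = kmr_priors(),
                         control = kmr_control(iter = 2000, burnin = 1000),
                         master_seed = 1, scenario_id = "scenario",
                         checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"), reps >= 1)
  bad <- setdiff(models, kmr_models)
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "),
                        "; valid models: ", paste(kmr_models, collapse = ", "))
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)
  per_rep <- vector("list", reps)
  failures <- 0L
  for (r in seq_len(reps)) {
    ck <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, sprintf("rep_%04d.csv", r)) else NULL
    if (!is.null(ck) && file.exists(ck)) {
      per_rep[[r]] <- utils::read.csv(ck, stringsAsFactors = FALSE)
      next
    }
    res <- tryCatch({
      sp <- spec
      sp$seed <- derive_seed(master_seed, r)
      gen <- generate_dataset(sp)
      rows <- lapply(models, function(model) {
        ctl <- control
        ctl$seed <- derive_seed(master_seed, 1000L + 17L * r +
                                  match(model, kmr_models))
        fitobj <- fit_model(model, gen$dataset, priors, ctl)
        est <- model_effect_estimates(fitobj, model, gen$dataset, gen$plan)
        ev <- evaluate_fit(est, gen$truth)
        ev$model <- model
        ev
      })
      out <- do.call(rbind, rows)
      out$rep <- r
      out
    }, error = function(e) {
      warning("replicate ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) {
      failures <- failures + 1L
    } else {
      per_rep[[r]] <- res
      if (!is.null(ck)) utils::write.csv(res, ck, row.names = FALSE)
    }
    if (verbose) message("replicate ", r, "/", reps, " done")
  }
  all_rows <- do.call(rbind, per_rep)
  if (is.null(all_rows)) stop("all replicates failed")
  agg <- lapply(split(all_rows, list(all_rows$model, all_rows$effect_type),
                      drop = TRUE), function(d) {
    nr <- nrow(d)
    data.frame(scenario = scenario_id, model = d$model[1L],
               effect_type = d$effect_type[1L],
               rmse = mean(d$rmse), rmse_se = stats::sd(d$rmse) / sqrt(nr),
               coverage = mean(d$coverage),
               coverage_se = stats::sd(d$coverage) / sqrt(nr),
               width = mean(d$width), width_se = stats::sd(d$width) / sqrt(nr),
               reps = nr, failures = failures)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  class(out) <- c("metrics_table", "data.frame")
  attr(out, "replicates") <- all_rows
  out
}

effect_type_order <- c("surface", "group_total", "group_single",
                       "diff_total", "diff_single")
effect_type_labels <- c(
  surface = "Exposure-response surface",
  group_total = "Group-specific total mixture effect",
  group_single = "Group-specific single-exposure effect",
  diff_total = "Between-group differences in total mixture effect",
  diff_single = "Between-group differences in single-exposure effect")

#' Arrange a metrics table as a model-comparison report
#'
#' Orders rows into effect-type blocks (surface, group-specific total and
#' single-exposure effects, between-group differences) with models in a
#' fixed order within each block and one RMSE/coverage/width column triple
#' per scenario.
#'
#' @param table A `metrics_table` (possibly row-bound over scenarios).
#' @return A data.frame of class `kmr_report`, one row per (effect type,
#'   model), wide over scenarios.
#' @export
compare_models <- function(table) {
  if (!nrow(table)) {
    out <- data.frame()
    class(out) <- c("kmr_report", "data.frame")
    return(out)
  }
  scen <- unique(table$scenario)
  base <- unique(table[, c("effect_type", "model")])
  base <- base[order(match(base$effect_type, effect_type_order),
                     match(base$model, kmr_models)), ]
  out <- base
  for (s in scen) {
    sub <- table[table$scenario == s, ]
    i <- match(paste(base$effect_type, base$model),
               paste(sub$effect_type, sub$model))
    out[[paste0(s, ".rmse")]] <- sub$rmse[i]
    out[[paste0(s, ".coverage")]] <- sub$coverage[i]
    out[[paste0(s, ".width")]] <- sub$width[i]
  }
  rownames(out) <- NULL
  class(out) <- c("kmr_report", "data.frame")
  out
}

#' @export
print.kmr_report <- function(x, digits = 2, ...) {
  if (!nrow(x)) {
    cat("empty report\n")
    return(invisible(x))
  }
  for (et in intersect(effect_type_order, unique(x$effect_type))) {
    cat(effect_type_labels[[et]], "\n")
    sub <- x[x$effect_type == et, -1L]
    print.data.frame(format(sub, digits = digits), row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}
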