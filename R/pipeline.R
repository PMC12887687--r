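# Orchestration: run configuration, the staged end-to-end analysis from raw
# tables to a result bundle, cohort summaries, and table writers.

#' Run configuration with full defaulting
#'
#' Every analysis parameter (windows, matching tolerance, network
#' thresholds, test level, correction family, model options, censor date,
#' seed) lives here so sensitivity analyses need no code changes. A config
#' can also be read from YAML/JSON via `path`.
#'
#' @param path Optional YAML (or JSON) file whose entries override defaults.
#' @param ... Direct overrides (take precedence over the file).
#' @return List of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    windows = default_windows(),
    matching_tolerance = 1.0,
    network = list(min_node_prev = 0.01, min_edge_count = NULL,
                   edge_method = "count", min_phi = 0.1, level = "code"),
    alpha = 0.05,
    prevalence_floor = 0.005,
    or_cap = 3,
    censor_date = as.Date("2024-04-30"),
    fracture_stem = "S72",
    seed = 1L,
    post_horizon = 10
  )
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    for (k in names(file_cfg)) {
      cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(file_cfg[[k]])) {
        utils::modifyList(cfg[[k]], file_cfg[[k]])
      } else {
        file_cfg[[k]]
      }
    }
    if (!is.null(file_cfg$censor_date)) {
      cfg$censor_date <- as.Date(file_cfg$censor_date)
    }
  }
  dots <- list(...)
  for (k in names(dots)) cfg[[k]] <- dots[[k]]
  structure(cfg, class = "run_config")
}

.stage <- function(log, name, ...) {
  msg <- sprintf(...)
  message(sprintf("[%s] %s", name, msg))
  c(log, stats::setNames(list(msg), name))
}

#' Run the full temporal comorbidity analysis
#'
#' Stages, in order: ingest and first-instance deduplication; overall
#' diagnosis resolution; control matching (AD and VaD separately, disjoint
#' control sets, placeholder index dates); hip-fracture control-disease
#' cohort with its own controls; temporal mapping of all comorbidities;
#' Mann-Whitney prevalence comparison at code and block level with
#' Bonferroni correction; per-window co-occurrence networks, degree
#' centrality and characteristic conditions with dual-control validation;
#' per-window logistic regression with odds ratios and cross-validated
#' AUROC; Cox time-to-death; PRS group comparison when scores are supplied.
#' Each stage logs its counts; empty subtype stages are skipped with a
#' recorded reason.
#'
#' @param participants,diagnoses Input tables (paths or `data.table`s with
#'   the documented schemas).
#' @param config A [run_config()].
#' @param prs Optional PRS table (`id`, `prs`) or path.
#' @param out_dir Optional output directory; when given, all bundle tables
#'   are written as CSV (networks additionally as edge lists) plus the
#'   serialized config and log.
#' @return A `result_bundle` list: `config`, `assignments`, `pairs`,
#'   `summary`, `prevalence` (code/block), `networks`, `characteristic`,
#'   `or_tables`, `auroc`, `survival`, `prs`, `log`.
#' @export
run_pipeline <- function(participants, diagnoses, config = run_config(),
                         prs = NULL, out_dir = NULL) {
  log <- list()
  if (is.character(participants)) participants <- read_participants(participants)
  if (is.character(diagnoses)) {
    diagnoses <- read_diagnoses(diagnoses)
  } else {
    diagnoses <- .normalize_diagnoses(diagnoses)
  }
  if (is.character(prs)) prs <- data.table::fread(prs, colClasses = list(character = "id"))
  participants <- data.table::as.data.table(participants)
  log <- .stage(log, "ingest", "%d participants, %d first-instance diagnoses",
                nrow(participants), nrow(diagnoses))

  # --- diagnosis resolution ------------------------------------------------
  assignments <- build_dementia_cohort(participants, diagnoses)
  log <- .stage(log, "resolve", "AD=%d VaD=%d excluded=%d none=%d",
                sum(assignments$label == "AD"), sum(assignments$label == "VaD"),
                sum(assignments$label == "excluded"),
                sum(assignments$label == "none"))

  # --- matching ------------------------------------------------------------
  pool <- assignments[label == "none"]
  pairs <- list(); used <- character(0)
  for (g in c("AD", "VaD")) {
    cs <- assignments[label == g]
    if (!nrow(cs)) { log <- .stage(log, paste0("match_", g), "empty cohort, skipped"); next }
    pr <- match_controls(cs, pool[!id %in% used],
                         tolerance_years = config$matching_tolerance,
                         seed = config$seed)
    used <- c(used, pr$control_id)
    pairs[[g]] <- pr[, cohort := g]
    log <- .stage(log, paste0("match_", g), "%d/%d cases matched", nrow(pr), nrow(cs))
  }
  pairs <- data.table::rbindlist(pairs)

  # --- control-disease cohort ---------------------------------------------
  cd <- build_control_disease_cohort(participants, diagnoses,
                                     fracture_stem = config$fracture_stem)
  cd_pairs <- NULL
  if (nrow(cd)) {
    cd_pool <- pool[!id %in% c(used, cd$id)]
    cd_pairs <- match_controls(cd, cd_pool,
                               tolerance_years = config$matching_tolerance,
                               seed = config$seed)
    log <- .stage(log, "control_disease", "%d fracture cases, %d matched",
                  nrow(cd), nrow(cd_pairs))
  } else {
    log <- .stage(log, "control_disease", "empty cohort, validation skipped")
  }

  # control assignments inherit the case's index date (placeholder flag date)
  ctrl_assign <- function(pr) {
    merge(assignments[, .(id, sex, birth_year, death_date)],
          pr[, .(id = control_id, index_date)], by = "id")[,
      age_at_index := as.numeric(index_date - birth_date(birth_year)) / 365.25][]
  }

  # --- temporal mapping ----------------------------------------------------
  windows <- config$windows
  all_index <- data.table::rbindlist(list(
    assignments[label %in% c("AD", "VaD"), .(id, index_date)],
    pairs[, .(id = control_id, index_date)],
    if (nrow(cd)) cd[, .(id, index_date)],
    if (!is.null(cd_pairs)) cd_pairs[, .(id = control_id, index_date)]
  ))
  offsets <- map_event_offsets(diagnoses, all_index,
                               drop_stems = config$fracture_stem)
  log <- .stage(log, "temporal", "%d comorbidity events mapped for %d participants",
                nrow(offsets), length(unique(offsets$id)))

  cohort_ids <- list()
  for (g in c("AD", "VaD")) {
    cohort_ids[[g]] <- assignments[label == g & id %in% pairs[cohort == g, case_id], id]
    cohort_ids[[paste0("control_", g)]] <- pairs[cohort == g, control_id]
  }
  if (nrow(cd) && !is.null(cd_pairs) && nrow(cd_pairs)) {
    cohort_ids[["hip"]] <- cd[id %in% cd_pairs$case_id, id]
    cohort_ids[["control_hip"]] <- cd_pairs$control_id
  }

  pm <- function(ids, w, level) {
    build_presence_matrix(offsets, ids, w, level = level, windows = windows)
  }

  # --- prevalence stats (whole mapped horizon = widest post window) --------
  # dementia overall vs controls at code and block level, plus per-subtype
  # code-level comparisons whose significant sets feed that subtype's models
  full_w <- windows[.N]$label
  dem_ids <- c(cohort_ids$AD, cohort_ids$VaD)
  ctl_ids <- c(cohort_ids$control_AD, cohort_ids$control_VaD)
  prevalence <- list()
  for (lv in c("code", "block")) {
    prevalence[[lv]] <- compare_prevalence(
      pm(dem_ids, full_w, lv), pm(ctl_ids, full_w, lv), level = lv,
      alpha = config$alpha, prevalence_floor = config$prevalence_floor)
  }
  mwu_sig_by <- list()
  for (g in c("AD", "VaD")) {
    if (!length(cohort_ids[[g]])) next
    prevalence[[paste0("code_", g)]] <- compare_prevalence(
      pm(cohort_ids[[g]], full_w, "code"),
      pm(cohort_ids[[paste0("control_", g)]], full_w, "code"),
      alpha = config$alpha, prevalence_floor = config$prevalence_floor)
    mwu_sig_by[[g]] <- prevalence[[paste0("code_", g)]][significant == TRUE,
                                                        condition]
  }
  mwu_sig <- prevalence$code[significant == TRUE, condition]
  log <- .stage(log, "prevalence",
                "significant code-level: %d overall, %d AD, %d VaD (of %d tested); %d block-level",
                length(mwu_sig), length(mwu_sig_by$AD %||% character(0)),
                length(mwu_sig_by$VaD %||% character(0)),
                nrow(prevalence$code), sum(prevalence$block$significant))

  # --- networks + characteristic conditions --------------------------------
  nw <- config$network
  build_nets <- function(ids, cohort) {
    stats::setNames(lapply(windows$label, function(w) {
      build_cooccurrence_network(pm(ids, w, nw$level),
                                 min_node_prev = nw$min_node_prev,
                                 min_edge_count = nw$min_edge_count,
                                 edge_method = nw$edge_method,
                                 min_phi = nw$min_phi, cohort = cohort)
    }), windows$label)
  }
  networks <- lapply(stats::setNames(names(cohort_ids), names(cohort_ids)),
                     function(g) build_nets(cohort_ids[[g]], g))
  disease_set <- NULL
  if (!is.null(networks$hip)) {
    disease_set <- control_disease_characteristic_set(networks$hip,
                                                      networks$control_hip)
  }
  characteristic <- data.table::rbindlist(lapply(c("AD", "VaD"), function(g) {
    if (is.null(networks[[g]])) return(NULL)
    cc <- characteristic_conditions(networks[[g]],
                                    networks[[paste0("control_", g)]],
                                    disease_characteristic = disease_set,
                                    mwu_significant = mwu_sig_by[[g]])
    if (nrow(cc)) cc[, cohort := g]
    cc
  }), fill = TRUE)
  if (nrow(characteristic) && nw$level == "code") {
    characteristic[, chapter := code_to_chapter(condition)]
  }
  log <- .stage(log, "networks", "characteristic conditions: %d (validated: %d)",
                nrow(characteristic), sum(characteristic$validated %||% logical(0)))

  # --- per-window logistic regression --------------------------------------
  or_tables <- list(); auroc <- list()
  pre_windows <- windows[kind == "pre", label]
  covf <- function(a) data.frame(age = a$age_at_index, sex = a$sex)
  for (g in c("AD", "VaD")) {
    if (!length(cohort_ids[[g]])) next
    case_a <- assignments[id %in% cohort_ids[[g]]][order(match(id, cohort_ids[[g]]))]
    ctrl_a <- ctrl_assign(pairs[cohort == g])
    ctrl_a <- ctrl_a[order(match(id, cohort_ids[[paste0("control_", g)]]))]
    for (w in pre_windows) {
      ids <- c(case_a$id, ctrl_a$id)
      X <- presence_indicator(pm(ids, w, "code"))
      y <- c(rep(1L, nrow(case_a)), rep(0L, nrow(ctrl_a)))
      cov <- rbind(covf(case_a), covf(ctrl_a))
      sig_g <- union(mwu_sig, mwu_sig_by[[g]])
      Xs <- X[, colnames(X) %in% sig_g, drop = FALSE]
      if (!ncol(Xs) || !any(colSums(Xs) > 0)) next
      fit <- tryCatch(
        fit_window_logistic(X, y, covariates = cov, mwu_significant = sig_g,
                            or_cap = config$or_cap, alpha = config$alpha),
        error = function(e) NULL)
      if (is.null(fit)) next
      or_tables[[paste(g, w)]] <- fit$results[, `:=`(cohort = g, window = w)]
      auroc[[paste(g, w)]] <- data.table::data.table(
        cohort = g, window = w,
        auroc = tryCatch(cv_auroc(Xs, y, covariates = cov, seed = config$seed),
                         error = function(e) NA_real_))
    }
  }
  or_tables <- data.table::rbindlist(or_tables, fill = TRUE)
  auroc <- data.table::rbindlist(auroc)
  log <- .stage(log, "regression", "%d condition-window OR estimates", nrow(or_tables))

  # --- survival ------------------------------------------------------------
  surv_data <- data.table::rbindlist(list(
    assignments[id %in% dem_ids][, group := "dementia"],
    ctrl_assign(pairs)[, group := "control"]), fill = TRUE)
  survival_tab <- tryCatch(
    cox_time_to_death(surv_data, censor_date = config$censor_date),
    error = function(e) { log <<- .stage(log, "survival", "skipped: %s",
                                         conditionMessage(e)); NULL })
  if (!is.null(survival_tab)) {
    log <- .stage(log, "survival", "%d events", survival_tab$n_events[1])
  }

  # --- PRS -----------------------------------------------------------------
  prs_tab <- NULL
  if (!is.null(prs)) {
    sc <- merge(data.table::as.data.table(prs)[, .(id, prs)],
                data.table::rbindlist(list(
                  assignments[id %in% cohort_ids$AD, .(id, group = "AD")],
                  assignments[id %in% cohort_ids$VaD, .(id, group = "VaD")],
                  data.table::data.table(id = ctl_ids, group = "control"))),
                by = "id")
    prs_tab <- compare_prs(sc)
    log <- .stage(log, "prs", "%d pairwise comparisons", nrow(prs_tab))
  }

  summary_tab <- summarize_cohort(assignments, participants, diagnoses,
                                  censor_date = config$censor_date)

  bundle <- structure(list(
    config = config, assignments = assignments, pairs = pairs,
    control_disease = cd, control_disease_pairs = cd_pairs,
    summary = summary_tab, prevalence = prevalence, networks = networks,
    characteristic = characteristic, or_tables = or_tables, auroc = auroc,
    survival = survival_tab, prs = prs_tab, log = log,
    seed = config$seed, version = as.character(utils::packageVersion("comorbmap"))),
    class = "result_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("result_bundle\n")
  for (nm in names(x$log)) cat(sprintf("  [%s] %s\n", nm, x$log[[nm]]))
  invisible(x)
}

#' Summarize a resolved cohort
#'
#' Per-label counts with exclusion reasons, deceased fractions, the median
#' and IQR of each participant's inpatient record span (first to last
#' event, years), and the distribution of the number of distinct dementia
#' subtype categories per participant with any dementia code.
#'
#' @param assignments From [build_dementia_cohort()].
#' @param participants,diagnoses Input tables.
#' @param censor_date Deaths after this date count as alive.
#' @return List of `data.table`s: `counts`, `deceased`, `record_span`,
#'   `subtype_multiplicity`.
#' @export
summarize_cohort <- function(assignments, participants, diagnoses,
                             censor_date = as.Date("2024-04-30")) {
  a <- data.table::as.data.table(assignments)
  d <- data.table::as.data.table(diagnoses)
  counts <- a[, .N, by = .(label, reason)][order(label, reason)]
  a[, deceased := !is.na(death_date) & death_date <= as.Date(censor_date)]
  deceased <- a[, .(n = .N, deceased = sum(deceased),
                    deceased_fraction = mean(deceased)), by = label]
  span <- d[, .(span = as.numeric(max(date) - min(date)) / 365.25), by = id]
  span <- merge(span, a[, .(id, label)], by = "id")
  record_span <- span[, .(median_span = stats::median(span),
                          iqr_span = stats::IQR(span)), by = label]
  ncat <- d[, .(ncat = length(unique(dementia_category(code)[
    dementia_category(code) != "none"]))), by = id]
  mult <- ncat[ncat > 0, .N, by = .(ncat = pmin(ncat, 4L))][order(ncat)]
  mult[, ncat := c("1", "2", "3", "4+")[ncat]]
  list(counts = counts, deceased = deceased, record_span = record_span,
       subtype_multiplicity = mult)
}

#' Write a result bundle to disk
#'
#' All tables as CSV with documented headers, networks as edge-list CSVs,
#' the characteristic table with its chapter column, the config as YAML and
#' the stage log as JSON. Every table is present or explicitly marked
#' skipped in the log.
#'
#' @param bundle A `result_bundle`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) if (!is.null(x) && nrow(x))
    data.table::fwrite(x, file.path(out_dir, name))
  w(bundle$assignments, "assignments.csv")
  w(bundle$pairs, "matched_pairs.csv")
  w(bundle$control_disease, "control_disease.csv")
  w(bundle$control_disease_pairs, "control_disease_pairs.csv")
  w(bundle$prevalence$code, "prevalence_code.csv")
  w(bundle$prevalence$block, "prevalence_block.csv")
  w(bundle$characteristic, "characteristic_conditions.csv")
  w(bundle$or_tables, "odds_ratios.csv")
  w(bundle$auroc, "auroc.csv")
  w(bundle$survival, "survival.csv")
  w(bundle$prs, "prs_comparisons.csv")
  for (tb in names(bundle$summary)) {
    w(bundle$summary[[tb]], paste0("summary_", tb, ".csv"))
  }
  net_dir <- file.path(out_dir, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  for (g in names(bundle$networks)) {
    for (wn in names(bundle$networks[[g]])) {
      net <- bundle$networks[[g]][[wn]]
      if (nrow(net$edges)) {
        export_network(net, path_csv = file.path(
          net_dir, sprintf("%s_%s.csv", g, gsub("[ +]", "", wn))))
      }
    }
  }
  cfg <- bundle$config
  cfg$windows <- as.data.frame(cfg$windows)
  cfg$censor_date <- as.character(cfg$censor_date)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  jsonlite::write_json(list(log = bundle$log, seed = bundle$seed,
                            version = bundle$version),
                       file.path(out_dir, "run_log.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
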