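# End-to-end orchestration: design -> simulate -> code -> fit -> importance
# -> reliability, with artifact output.

#' Default run configuration
#'
#' Three bundled experiments: `dce1` (five cessation-benefit topics x five
#' imagery types), `dce2` (five quitting-tips topics x the same imagery
#' types), both with 50 choice sets in 10 blocks of 5 and a follow-up wave;
#' `dce3` (four reproductive-health topics x four imagery types with
#' matching constraints: one topic fits all four images, the other three fit
#' three each, giving 13 profiles and 13 sets in 3 blocks of 5/4/4), baseline
#' only.
#'
#' @param n cohort size (default 1000).
#' @param seed master seed; every stage draws from a named substream.
#' @param retention follow-up retention probability (default 0.58).
#' @return A nested configuration list.
#' @export
default_config <- function(n = 1000L, seed = 20180206L, retention = 0.58) {
  ref <- reference_partworths()
  lev <- function(ex, attr) unique(ref$level[ref$experiment == ex &
                                               ref$attribute == attr])
  m3 <- matrix(TRUE, 4L, 4L)
  # one topic fits all four images; each other topic fits three:
  # the tips variant drops the family image, the family topic drops the
  # pregnancy image, the fertility topic drops the mom-with-baby image
  m3[2L, 3L] <- FALSE; m3[3L, 1L] <- FALSE; m3[4L, 2L] <- FALSE
  list(
    seed = as.integer(seed),
    cohort = list(n = as.integer(n), quota_quit_intention = 0.5),
    waves = list(retention = retention),
    experiments = list(
      dce1 = list(topics = lev("dce1", "topic"), images = lev("dce1", "imagery"),
                  match = NULL, k = 4L, block_sizes = rep(5L, 10L),
                  followup = TRUE),
      dce2 = list(topics = lev("dce2", "topic"), images = lev("dce2", "imagery"),
                  match = NULL, k = 4L, block_sizes = rep(5L, 10L),
                  followup = TRUE),
      dce3 = list(topics = lev("dce3", "topic"), images = lev("dce3", "imagery"),
                  match = m3, k = 4L, block_sizes = c(5L, 4L, 4L),
                  followup = FALSE)
    )
  )
}

#' Read a run configuration from YAML or JSON
#'
#' The file mirrors the structure of [default_config()]; a `match` entry is
#' given as a list of logical rows. Missing cohort/wave entries fall back to
#' the defaults.
#'
#' @param path file ending in `.yaml`, `.yml`, or `.json`.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  # YAML 1.1 parses a bare `n` key as boolean FALSE; map it back
  if (!is.null(raw$cohort) && "FALSE" %in% names(raw$cohort))
    names(raw$cohort)[names(raw$cohort) == "FALSE"] <- "n"
  if (is.null(raw$seed)) stop("config must set a seed", call. = FALSE)
  base <- default_config(n = raw$cohort$n %||% 1000L, seed = raw$seed,
                         retention = raw$waves$retention %||% 0.58)
  if (!is.null(raw$cohort$quota_quit_intention))
    base$cohort$quota_quit_intention <- raw$cohort$quota_quit_intention
  if (!is.null(raw$experiments)) {
    base$experiments <- lapply(raw$experiments, function(ex) {
      if (!is.null(ex$match) && !is.matrix(ex$match))
        ex$match <- do.call(rbind, lapply(ex$match, as.logical))
      ex$k <- as.integer(ex$k %||% 4L)
      ex$block_sizes <- as.integer(ex$block_sizes)
      ex$followup <- isTRUE(ex$followup)
      ex
    })
  }
  base
}

build_experiment_design <- function(name, ex, seed) {
  topics <- attribute_spec("topic", ex$topics, "topic")
  images <- attribute_spec("imagery", ex$images, "imagery")
  match <- if (!is.null(ex$match)) match_matrix(topics, images, ex$match)
  profiles <- enumerate_profiles(topics, images, match)
  d <- build_pairwise_balanced_design(profiles, ex$k,
                                      seed = substream_seed(seed, paste0("design:", name)))
  partition_into_blocks(d, ex$block_sizes,
                        seed = substream_seed(seed, paste0("blocks:", name)))
}

#' Run the full analysis pipeline
#'
#' Builds the designs, samples the cohort, simulates baseline (and, where
#' configured, follow-up) responses, codes them, applies the analytic-sample
#' filter with exclusion comparisons, fits the main-effects and interaction
#' mixed models per experiment and wave, computes utility-range importance,
#' and computes test-retest reliability for experiments with a follow-up
#' wave. Writes CSV/JSON artifacts and a manifest when `outdir` is given.
#' Fully deterministic for a fixed config.
#'
#' @param config configuration list from [default_config()] or
#'   [read_config()].
#' @param outdir optional output directory for artifacts.
#' @param models interaction blocks to fit besides the main-effects model.
#' @param quiet suppress progress messages.
#' @return A list with `designs`, `cohort`, `records`, `coded`, `samples`,
#'   `exclusion_tests`, `fits`, `importance`, `reliability`, and `files`.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         models = c("sex", "age", "topic_imagery"),
                         quiet = FALSE) {
  t_start <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed
  exps <- config$experiments
  designs <- lapply(names(exps), function(nm)
    build_experiment_design(nm, exps[[nm]], seed))
  names(designs) <- names(exps)
  for (nm in names(designs))
    say("design %s: %d profiles, %d sets, %d blocks", nm,
        nrow(designs[[nm]]$profiles), length(designs[[nm]]$sets),
        length(designs[[nm]]$blocks))
  n_blocks <- vapply(designs, function(d) length(d$blocks), integer(1))
  cohort <- sample_cohort(config$cohort$n,
                          quota_quit_intention = config$cohort$quota_quit_intention,
                          n_blocks = n_blocks,
                          seed = substream_seed(seed, "cohort"))
  say("cohort: %d respondents (%d quit-intenders)", nrow(cohort),
      sum(cohort$quit_intention_6mo))
  umods <- lapply(names(exps), function(nm) default_utility_model(nm))
  names(umods) <- names(exps)
  records <- list(); coded <- list(); samples <- list(); excl <- list()
  fits <- list(); importance <- list(); reliability <- list()
  for (nm in names(exps)) {
    base <- simulate_choices(cohort, designs[[nm]], umods[[nm]], experiment = nm,
                             seed = substream_seed(seed, paste0("choices:", nm)))
    waves <- list(baseline = base)
    if (isTRUE(exps[[nm]]$followup))
      waves$followup <- simulate_followup(cohort, base, designs[[nm]], umods[[nm]],
                                          retention = config$waves$retention,
                                          seed = substream_seed(seed, paste0("followup:", nm)))
    records[[nm]] <- do.call(rbind, waves)
    coded[[nm]] <- list(); samples[[nm]] <- list(); fits[[nm]] <- list()
    for (wv in names(waves)) {
      cw <- code_best_worst(waves[[wv]], designs[[nm]])
      fs <- filter_analytic_sample(waves[[wv]])
      samples[[nm]][[wv]] <- fs
      say("%s %s: %d records, analytic sample %d/%d (%.0f%%)", nm, wv,
          nrow(waves[[wv]]), length(fs$included),
          length(fs$included) + length(fs$excluded),
          100 * (1 - fs$prop_excluded))
      if (wv == "baseline" && length(fs$excluded) && length(fs$included))
        excl[[nm]] <- compare_excluded(cohort, fs$included, fs$excluded)
      cw_in <- cw[cw$respondent_id %in% fs$included, ]
      coded[[nm]][[wv]] <- cw
      fits[[nm]][[wv]] <- list(
        main = fit_mixed_model(cw_in, cohort, designs[[nm]], "none"))
      for (mdl in models)
        fits[[nm]][[wv]][[mdl]] <-
          fit_mixed_model(cw_in, cohort, designs[[nm]],
                          if (mdl == "topic_imagery") "topic_imagery" else mdl)
      say("%s %s: fitted %d models", nm, wv, length(fits[[nm]][[wv]]))
    }
    importance[[nm]] <- relative_importance(fits[[nm]]$baseline$main)
    if (isTRUE(exps[[nm]]$followup)) {
      keep <- intersect(samples[[nm]]$baseline$included,
                        samples[[nm]]$followup$included)
      cb <- coded[[nm]]$baseline
      cf <- coded[[nm]]$followup
      ag <- choice_agreement(cb[cb$respondent_id %in% keep, ],
                             cf[cf$respondent_id %in% keep, ])
      conc <- coefficient_concordance(fits[[nm]]$baseline$main,
                                      fits[[nm]]$followup$main)
      reliability[[nm]] <- list(agreement = ag, concordance = conc,
                                sweep = kappa_prevalence_sweep())
      say("%s reliability: agreement %.3f, kappa %.3f, concordance %.2f",
          nm, ag$percent_agreement, ag$kappa, conc$concordance)
    }
  }
  out <- list(designs = designs, cohort = cohort, records = records,
              coded = coded, samples = samples, exclusion_tests = excl,
              fits = fits, importance = importance, reliability = reliability,
              config = config, files = character(0))
  if (!is.null(outdir)) out$files <- write_artifacts(out, outdir)
  say("pipeline finished in %.1fs", as.numeric(Sys.time() - t_start, units = "secs"))
  invisible(out)
}

write_artifacts <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wcsv(res$cohort, "respondents.csv")
  wcsv(do.call(rbind, unname(res$records)), "choices.csv")
  for (nm in names(res$designs)) {
    p <- file.path(outdir, paste0("design_", nm, ".json"))
    write_design(res$designs[[nm]], p); files <- c(files, p)
    wcsv(design_table(res$designs[[nm]]), paste0("design_", nm, ".csv"))
  }
  for (nm in names(res$fits))
    for (wv in names(res$fits[[nm]]))
      for (mdl in names(res$fits[[nm]][[wv]]))
        wcsv(render_fit_table(res$fits[[nm]][[wv]][[mdl]]),
             sprintf("fit_%s_%s_%s.csv", nm, wv, mdl))
  imp <- do.call(rbind, lapply(names(res$importance), function(nm)
    cbind(experiment = nm, res$importance[[nm]])))
  wcsv(imp, "importance.csv")
  if (length(res$exclusion_tests)) {
    ex <- do.call(rbind, lapply(names(res$exclusion_tests), function(nm)
      cbind(experiment = nm, res$exclusion_tests[[nm]])))
    wcsv(ex, "exclusion_comparison.csv")
  }
  if (length(res$reliability)) {
    rel <- lapply(res$reliability, function(r) list(
      percent_agreement = r$agreement$percent_agreement,
      kappa = r$agreement$kappa, p_e = r$agreement$p_e,
      n_cells = r$agreement$n_cells,
      concordance = r$concordance$concordance,
      n_compared = r$concordance$n_compared))
    p <- file.path(outdir, "reliability.json")
    jsonlite::write_json(rel, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, p)
    wcsv(kappa_prevalence_sweep(), "kappa_sweep.csv")
  }
  cfgp <- file.path(outdir, "config.json")
  jsonlite::write_json(res$config, cfgp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  files <- c(files, cfgp)
  manifest <- list(seed = res$config$seed,
                   config_md5 = unname(tools::md5sum(cfgp)),
                   n_respondents = nrow(res$cohort),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   package_version = as.character(utils::packageVersion("bwdce")),
                   files = basename(files))
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(files, mp)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Publication-style coefficient table for one fit
#'
#' @param fit a `bw_fit`.
#' @return A data frame with `attribute`, `stratum`, `level`, `b`, `se`,
#'   `p`, `stars`, and a `b_se` display column like `"0.014 (0.004)"`, plus
#'   appended per-attribute joint-test rows.
#' @export
render_fit_table <- function(fit) {
  stopifnot(inherits(fit, "bw_fit"))
  pw <- fit$partworths
  tab <- data.frame(attribute = pw$attribute, stratum = pw$stratum,
                    level = pw$level,
                    b = round(pw$estimate, 3), se = round(pw$se, 3),
                    p = signif(pw$p, 3), stars = significance_stars(pw$p),
                    b_se = sprintf("%.3f%s (%.3f)", pw$estimate,
                                   significance_stars(pw$p), pw$se),
                    stringsAsFactors = FALSE)
  jt <- fit$joint_tests
  jt_rows <- data.frame(attribute = jt$term, stratum = "overall",
                        level = "(joint test)", b = NA_real_, se = NA_real_,
                        p = signif(jt$p, 3), stars = significance_stars(jt$p),
                        b_se = sprintf("chi2(%d) = %.2f", jt$df, jt$statistic),
                        stringsAsFactors = FALSE)
  rbind(tab, jt_rows)
}

#' Attribute-importance summary table across experiments
#'
#' @param importance named list of [relative_importance()] results.
#' @return A data frame with whole-percent shares per experiment summing to
#'   about 100.
#' @export
render_importance_table <- function(importance) {
  do.call(rbind, lapply(names(importance), function(nm)
    data.frame(experiment = nm,
               attribute = importance[[nm]]$attribute,
               share_pct = importance[[nm]]$share_pct,
               stringsAsFactors = FALSE)))
}
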