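# End-to-end orchestration: configuration, the full design -> simulate ->
# classify -> qPCR -> compare workflow, and group-level summaries.

#' Run configuration
#'
#' Bundles every tunable of an end-to-end run. The configuration round-trips
#' through YAML and every stage output records its hash, so a rerun with the
#' same config (and seed) is reproducible.
#'
#' @param seed Integer master seed.
#' @param retention_pct Doped-oligo retention percentage.
#' @param n_library Number of library draws.
#' @param depth Simulated molecules per distinct variant.
#' @param error_rate Per-base read substitution error rate.
#' @param read_len Read length.
#' @param cutoff Read-depth cutoff for reliable estimates.
#' @param p_noncleavage True non-cleavage probability.
#' @param decay Per-substitution decay of the true loxP cleavage probability.
#' @param qpcr_variants Number of variants re-measured by simulated qPCR.
#' @param out_dir Output directory for stage files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, retention_pct = 84.7, n_library = 2000L,
                       depth = 2000L, error_rate = 0, read_len = 150L,
                       cutoff = 500L, p_noncleavage = 0.035, decay = 0.85,
                       qpcr_variants = 10L, out_dir = tempfile("loxscreen_")) {
  cfg <- list(seed = as.integer(seed), retention_pct = retention_pct,
              n_library = as.integer(n_library), depth = as.integer(depth),
              error_rate = error_rate, read_len = as.integer(read_len),
              cutoff = as.integer(cutoff), p_noncleavage = p_noncleavage,
              decay = decay, qpcr_variants = as.integer(qpcr_variants),
              out_dir = out_dir,
              version = as.character(utils::packageVersion("loxscreen")))
  structure(cfg, class = "run_config")
}

#' Hash of a run configuration
#'
#' Stable content hash over every field except the output directory (paths
#' differ across machines without changing the run).
#'
#' @param config A [run_config()].
#' @return A character hash.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rlang::hash(unclass(config)[setdiff(names(config), "out_dir")])
}

#' @rdname run_config
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

write_stage_tsv <- function(x, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# loxscreen config_hash=%s seed=%d",
                     config_hash(config), config$seed), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-substitution-group rate summary with adjacent-group t-tests
#'
#' Groups per-variant cleavage-rate estimates by substitution count, reports
#' group mean/sd/n, and runs Welch two-tailed t-tests between adjacent
#' groups (the loss of Cre recognition should deepen as substitutions
#' accumulate). Groups with fewer than 2 members are skipped with a warning.
#'
#' @param estimates Estimate table from [estimate_library()] (or any
#'   data.frame with `n_substitutions` and `cleavage_rate_pct`).
#' @param min_group Minimum members for a group to enter a test.
#' @return A list: `groups` (data.frame k/n/mean/sd) and `tests`
#'   (data.frame k1/k2/t/df/p_value for adjacent tested groups).
#' @export
group_rate_summary <- function(estimates, min_group = 2L) {
  stopifnot(all(c("n_substitutions", "cleavage_rate_pct") %in%
                  names(estimates)))
  est <- estimates[!is.na(estimates$cleavage_rate_pct), ]
  ks <- sort(unique(est$n_substitutions))
  groups <- do.call(rbind, lapply(ks, function(k) {
    v <- est$cleavage_rate_pct[est$n_substitutions == k]
    data.frame(n_substitutions = k, n = length(v), mean = mean(v),
               sd = stats::sd(v))
  }))
  testable <- groups$n_substitutions[groups$n >= min_group]
  if (length(testable) < 2) {
    warning("fewer than 2 groups with enough members; no t-tests run")
    return(list(groups = groups,
                tests = data.frame(k1 = integer(0), k2 = integer(0),
                                   t = numeric(0), df = numeric(0),
                                   p_value = numeric(0))))
  }
  skipped <- setdiff(groups$n_substitutions, testable)
  if (length(skipped) > 0) {
    warning(sprintf("groups skipped (fewer than %d members): %s", min_group,
                    paste(skipped, collapse = ", ")))
  }
  tests <- do.call(rbind, lapply(seq_len(length(testable) - 1), function(i) {
    k1 <- testable[i]; k2 <- testable[i + 1]
    ht <- stats::t.test(est$cleavage_rate_pct[est$n_substitutions == k1],
                        est$cleavage_rate_pct[est$n_substitutions == k2],
                        alternative = "two.sided", var.equal = FALSE)
    data.frame(k1 = k1, k2 = k2, t = unname(ht$statistic),
               df = unname(ht$parameter), p_value = ht$p.value)
  }))
  list(groups = groups, tests = tests)
}

#' Run the whole screen workflow on synthetic data
#'
#' design -> simulate -> classify -> simulated qPCR -> compare, writing one
#' TSV per report component under `config$out_dir` (each stamped with the
#' config hash and seed, never with timestamps, so a rerun is byte-identical):
#' the substitution-count histogram against the binomial design model,
#' per-class coverage, per-position base composition, the per-variant
#' estimate table ranked by cleavage rate, the substitution-group summary,
#' and the NGS-vs-qPCR concordance scatter.
#'
#' @param config A [run_config()].
#' @return A list of class `lox_report` with all components plus `paths` of
#'   the files written.
#' @export
run_end_to_end <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  lib <- run("design", sample_library(design_spec(config$retention_pct),
                                      config$n_library, seed = config$seed))
  variants <- unique(lib$sequence)
  theory <- substitution_count_distribution(config$retention_pct)
  obs <- tabulate(lib$n_substitutions + 1L, nbins = RBE_LEN + 1L)
  hist_tab <- data.frame(n_substitutions = 0:RBE_LEN,
                         observed = obs,
                         observed_frac = obs / sum(obs),
                         theoretical_frac = as.numeric(theory))
  cov_tab <- data.frame(
    n_substitutions = 0:RBE_LEN,
    class_size = vapply(0:RBE_LEN, enumerate_variant_class, numeric(1)),
    coverage_pct = vapply(0:RBE_LEN, function(k) coverage_rate(variants, k),
                          numeric(1)))
  comp <- position_composition(lib$sequence)

  cfg_seed <- config$seed
  construct <- run("simulate", construct_config(cfg_seed))
  truth <- default_truth(variants, p_noncleavage = config$p_noncleavage,
                         decay = config$decay, n_molecules = config$depth)
  sim <- run("simulate", generate_fastq(truth, config$out_dir,
                                        config = construct,
                                        read_len = config$read_len,
                                        error_rate = config$error_rate,
                                        seed = cfg_seed))

  est <- run("classify", estimate_library(sim$r1, sim$r2, construct,
                                          cutoff = config$cutoff))
  grp <- run("classify", group_rate_summary(est))

  n_q <- min(config$qpcr_variants, nrow(truth))
  q_idx <- with_seed(cfg_seed + 1L, sample.int(nrow(truth), n_q))
  q_truth <- truth[q_idx, , drop = FALSE]
  qpcr <- run("qpcr", simulate_qpcr(q_truth, seed = cfg_seed + 2L))
  merged <- merge(est[, c("variant", "cleavage_rate_pct")], qpcr,
                  by = "variant")
  conc <- run("compare", concordance(merged$cleavage_rate_pct,
                                     merged$loxP_cleavage_pct))

  paths <- list(
    histogram = file.path(config$out_dir, "substitution_histogram.tsv"),
    coverage = file.path(config$out_dir, "coverage.tsv"),
    composition = file.path(config$out_dir, "position_composition.tsv"),
    estimates = file.path(config$out_dir, "estimates.tsv"),
    groups = file.path(config$out_dir, "group_summary.tsv"),
    concordance = file.path(config$out_dir, "qpcr_concordance.tsv"),
    config = file.path(config$out_dir, "run_config.yaml"))
  write_stage_tsv(hist_tab, paths$histogram, config)
  write_stage_tsv(cov_tab, paths$coverage, config)
  comp_tab <- data.frame(position = seq_len(nrow(comp)), comp)
  write_stage_tsv(comp_tab, paths$composition, config)
  est_out <- est
  est_out$cleavage_rate_pct <- round1(est_out$cleavage_rate_pct)
  est_out$non_cleavage_rate_pct <- round1(est_out$non_cleavage_rate_pct)
  write_stage_tsv(est_out, paths$estimates, config)
  grp_tab <- merge(grp$groups,
                   rbind(grp$tests[, c("k1", "p_value")],
                         data.frame(k1 = NA_integer_, p_value = NA_real_)),
                   by.x = "n_substitutions", by.y = "k1", all.x = TRUE)
  write_stage_tsv(grp_tab, paths$groups, config)
  write_stage_tsv(conc$data, paths$concordance, config)
  write_run_config(config, paths$config)

  structure(
    list(config = config, config_hash = config_hash(config),
         histogram = hist_tab, coverage = cov_tab, composition = comp,
         truth = truth, estimates = est, group_summary = grp,
         qpcr = qpcr, concordance = conc, paths = paths),
    class = "lox_report"
  )
}

#' @export
print.lox_report <- function(x, ...) {
  n_pass <- sum(x$estimates$passes_cutoff)
  cat(sprintf(
    paste0("loxscreen end-to-end report (config %s)\n",
           "  %d library draws, %d distinct variants, %d passing the >%d-read cutoff\n",
           "  mean non-cleavage rate %.1f%%; NGS-vs-qPCR R^2 = %.4f (n = %d)\n"),
    substr(x$config_hash, 1, 8), x$config$n_library, nrow(x$estimates),
    n_pass, x$config$cutoff,
    mean(x$estimates$non_cleavage_rate_pct, na.rm = TRUE),
    x$concordance$r_squared, x$concordance$n))
  invisible(x)
}
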