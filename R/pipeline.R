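# End-to-end pipeline driver: simulate (or load) -> phase -> QC -> ML tree ->
# LRT -> per-site parsimony -> PHI -> mutation rate -> haplotype groups.
# Identical config + seed gives a byte-identical report payload.

ALL_STAGES <- c("phase", "qc", "tree", "lrt", "parsimony", "phi",
                "rate", "haplotypes")

#' Build a pipeline configuration
#'
#' @param stages which analysis stages to run (subset of
#'   `phase, qc, tree, lrt, parsimony, phi, rate, haplotypes`).
#' @param simulate list of simulator settings (`enabled`, `n_taxa`,
#'   `seq_length`, `alpha`, `p_inv`, `mean_branch`, `mixture_ratio`,
#'   `noise_sd`, `missing_fraction`).  When enabled, inputs are generated;
#'   otherwise `paths$fasta` (and optionally `paths$peaks`) are read.
#' @param model list: `spec` (tree-stage model), `k` (gamma categories),
#'   `search` ("nni" or "fixed"), `lrt_null`, `lrt_alt`, `level`.
#' @param thresholds list: `minor_ratio_min`, `max_missing`, `n_perm`,
#'   `phi_window`.
#' @param frame reading-frame offset for codon annotations.
#' @param years divergence time for the mutation-rate stage.
#' @param seed master integer seed; every stochastic stage derives its own
#'   stream from it deterministically.
#' @param paths list: `fasta`, `peaks`, `out` (report JSON), all optional.
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(stages = ALL_STAGES,
                            simulate = list(),
                            model = list(),
                            thresholds = list(),
                            frame = 0L, years = 11,
                            seed = 1L, paths = list()) {
  stopifnot(all(stages %in% ALL_STAGES))
  sim_def <- list(enabled = TRUE, n_taxa = 8L, seq_length = 500L,
                  alpha = 0.1, p_inv = 0.3, mean_branch = 0.03,
                  mixture_ratio = 0.7, noise_sd = 0.02,
                  missing_fraction = 0.1)
  mod_def <- list(spec = "GTR+G+I", k = 8L, search = "nni",
                  lrt_null = "GTR+I", lrt_alt = "GTR+G+I", level = 0.001)
  thr_def <- list(minor_ratio_min = 0.25, max_missing = 0.18,
                  n_perm = 199L, phi_window = 100L)
  cfg <- list(stages = stages,
              simulate = utils::modifyList(sim_def, simulate),
              model = utils::modifyList(mod_def, model),
              thresholds = utils::modifyList(thr_def, thresholds),
              frame = as.integer(frame), years = years,
              seed = as.integer(seed),
              paths = utils::modifyList(list(fasta = NULL, peaks = NULL,
                                             out = NULL), paths))
  stopifnot(cfg$model$k >= 1L,
            cfg$thresholds$max_missing >= 0, cfg$thresholds$max_missing <= 1)
  class(cfg) <- "analysis_config"
  cfg
}

#' Read a pipeline configuration from JSON
#' @param path JSON file
#' @return an [analysis_config()]
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, raw[intersect(names(raw), names(formals(analysis_config)))])
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

stage_seed <- function(cfg, stage) {
  # deterministic per-stage split of the master seed, kept inside 32 bits
  (cfg$seed * 131L + match(stage, c("simulate", ALL_STAGES)) * 7L) %%
    .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Stages run in the fixed order simulate -> phase -> QC -> tree -> LRT ->
#' parsimony -> PHI -> rate -> haplotypes; each enabled stage contributes
#' exactly one report section.  A stage failure aborts the run with the
#' stage name and cause; if an output path is configured, a partial report
#' carrying a failure marker is written first.
#'
#' @param config an [analysis_config()].
#' @return list of class `"pipeline_report"`: one section per enabled
#'   stage, plus `provenance` (config hash, master seed, per-stage seeds,
#'   package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  report <- list(provenance = list(
    config_hash = config_hash(config),
    seed = config$seed,
    stage_seeds = stats::setNames(
      lapply(c("simulate", ALL_STAGES), function(s) stage_seed(config, s)),
      c("simulate", ALL_STAGES)),
    package_version = as.character(utils::packageVersion("virophase"))))

  fail <- function(stage, err) {
    report$failure <- list(stage = stage, message = conditionMessage(err))
    if (!is.null(config$paths$out)) write_report(report, config$paths$out)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(err)), call. = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) fail(stage, e))
  }

  # ---- inputs ----
  sim <- config$simulate
  truth <- NULL
  peaks <- NULL
  if (isTRUE(sim$enabled)) {
    inp <- run_stage("simulate", {
      s <- stage_seed(config, "simulate")
      tr <- simulate_tree(sim$n_taxa, seed = s, mean_branch = sim$mean_branch)
      mdl <- subst_model(alpha = sim$alpha, p_inv = sim$p_inv,
                         k = config$model$k)
      aln <- evolve_sequences(tr, mdl, sim$seq_length, seed = s + 1L)
      seqs <- alignment_strings(aln)
      pk <- simulate_mixture_peaks(seqs[[1]], seqs[[2]],
                                   ratio = sim$mixture_ratio,
                                   noise_sd = sim$noise_sd, seed = s + 2L)
      masked <- inject_missing(seqs[[1]], sim$missing_fraction,
                               seed = s + 3L, mode = "ends")
      list(aln = aln, peaks = pk, tree = tr,
           masked_record = masked)
    })
    aln <- inp$aln
    peaks <- inp$peaks
    truth <- list(tree = write_newick(inp$tree),
                  masked_record = inp$masked_record)
  } else {
    aln <- run_stage("load", {
      if (is.null(config$paths$fasta)) {
        stop("no input: simulate disabled and paths$fasta unset")
      }
      read_fasta(config$paths$fasta)
    })
    if (!is.null(config$paths$peaks)) peaks <- read_peak_table(config$paths$peaks)
  }
  if (!is.null(truth)) report$provenance$simulated_truth <- truth

  enabled <- function(s) s %in% config$stages

  if (enabled("phase")) {
    report$phase <- run_stage("phase", {
      if (is.null(peaks)) {
        list(skipped_reason = "no peak table supplied")
      } else {
        hs <- call_het_sites(peaks, config$thresholds$minor_ratio_min)
        ph <- phase_haplotypes(peaks, hs, id = "mixed_sample")
        list(n_het_sites = nrow(hs),
             het_positions = hs$position,
             n_haplotypes = ph$n_haplotypes,
             high = ph$high, low = ph$low)
      }
    })
  }

  if (enabled("qc")) {
    report$qc <- run_stage("qc", {
      seqs <- alignment_strings(aln)
      pass <- vapply(seqs, missing_fraction_ok, logical(1),
                     max_fraction = config$thresholds$max_missing)
      if (sum(pass) < 2L) stop("fewer than 2 records pass the missing-data rule")
      aln <- aln[names(seqs)[pass], ]
      list(n_in = length(seqs), n_pass = sum(pass),
           failed = names(seqs)[!pass],
             max_missing = config$thresholds$max_missing)
    })
  }

  ml_fit <- NULL
  if (enabled("tree")) {
    report$tree <- run_stage("tree", {
      ml_fit <- phylo_ml(aln, model = config$model$spec, k = config$model$k,
                          search = config$model$search)
      list(model = ml_fit$model_label, lnL = ml_fit$lnL,
           n_free_params = ml_fit$n_free_params,
           alpha = ml_fit$model$alpha, p_inv = ml_fit$model$p_inv,
           newick = write_newick(ml_fit$tree))
    })
  }

  if (enabled("lrt")) {
    report$lrt <- run_stage("lrt", {
      topo <- if (!is.null(ml_fit)) ml_fit$tree else NULL
      f0 <- phylo_ml(aln, model = config$model$lrt_null, k = config$model$k,
                     tree = topo, search = "fixed")
      # warm-start the richer model from the null optimum; the null lies on
      # the boundary of the alternative's parameter space, so its lnL is a
      # valid lower bound for the alternative's maximum
      f1 <- phylo_ml(aln, model = config$model$lrt_alt, k = config$model$k,
                     tree = f0$tree, search = "fixed")
      f1$lnL <- max(f1$lnL, f0$lnL)
      r <- lrt(f0, f1, level = config$model$level)
      list(null = config$model$lrt_null, alt = config$model$lrt_alt,
           lnL_null = f0$lnL, lnL_alt = f1$lnL,
           stat = r$stat, df = r$df, p_value = r$p_value,
           critical_value = r$critical_value, level = r$level,
           reject = r$reject)
    })
  }

  if (enabled("parsimony")) {
    report$parsimony <- run_stage("parsimony", {
      topo <- if (!is.null(ml_fit)) ml_fit$tree
              else nj_tree(jc_distance_matrix(aln))
      prof <- fitch_site_steps(aln, topo, frame = config$frame)
      cls <- classify_recurrent_aa_changes(prof, aln, frame = config$frame)
      list(total_steps = sum(prof$min_steps),
           n_variable_sites = sum(prof$min_steps > 0),
           max_steps = max(prof$min_steps),
           n_aa_change_sites = sum(cls$aa_change),
           n_recurrent_aa = sum(cls$recurrent_aa),
           steps = prof$min_steps)
    })
  }

  if (enabled("phi")) {
    report$phi <- run_stage("phi", {
      r <- phi_permutation_test(aln, window = config$thresholds$phi_window,
                                n_perm = config$thresholds$n_perm,
                                seed = stage_seed(config, "phi"))
      list(phi = r$phi, n_informative_pairs = r$n_informative_pairs,
           p_value = r$p_value, n_perm = r$n_perm,
           untestable = isTRUE(r$untestable))
    })
  }

  if (enabled("rate")) {
    report$rate <- run_stage("rate", {
      # first record stands in for the dated reference isolate
      seqs <- alignment_strings(aln)
      ref <- seqs[[1]]
      syn <- vapply(seqs[-1], function(s)
        count_synonymous_diffs(ref, s, frame = config$frame)$syn, integer(1))
      lo <- mutation_rate(min(syn), ncol(aln), config$years)
      hi <- mutation_rate(max(syn), ncol(aln), config$years)
      list(reference = names(seqs)[1], syn_range = range(syn),
           syn_mean = mean(syn), years = config$years,
           rate_lower = lo$rate, rate_upper = hi$rate)
    })
  }

  if (enabled("haplotypes")) {
    report$haplotypes <- run_stage("haplotypes", {
      g <- distinct_haplotypes(aln, policy = "strict")
      list(n_records = nrow(aln), n_distinct = g$n_distinct,
           groups = g$groups)
    })
  }

  class(report) <- "pipeline_report"
  if (!is.null(config$paths$out)) write_report(report, config$paths$out)
  report
}

#' Serialize a pipeline report to JSON
#' @param report a `pipeline_report`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_report <- function(report, path) {
  writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                              digits = NA, null = "null", na = "null"),
             path)
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  secs <- setdiff(names(x), c("provenance", "failure"))
  cat(sprintf("Pipeline report: %d section(s) [%s]\n",
              length(secs), paste(secs, collapse = ", ")))
  if (!is.null(x$failure)) {
    cat(sprintf("  FAILED at stage '%s': %s\n", x$failure$stage,
                x$failure$message))
  }
  if (!is.null(x$tree)) {
    cat(sprintf("  tree: %s, lnL = %.4f, alpha = %s\n", x$tree$model,
                x$tree$lnL, format(x$tree$alpha)))
  }
  if (!is.null(x$lrt)) {
    cat(sprintf("  LRT %s vs %s: 2dlnL = %.4f (reject: %s)\n",
                x$lrt$null, x$lrt$alt, x$lrt$stat, x$lrt$reject))
  }
  if (!is.null(x$phi)) {
    cat(sprintf("  PHI p = %s\n", format(x$phi$p_value)))
  }
  if (!is.null(x$haplotypes)) {
    cat(sprintf("  distinct haplotypes: %d / %d records\n",
                x$haplotypes$n_distinct, x$haplotypes$n_records))
  }
  invisible(x)
}
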