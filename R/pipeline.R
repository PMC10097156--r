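# Configuration-driven pipeline and the command-line surface.  Every
# stochastic step flows from the single config seed; results go to files,
# logs to stderr.

#' Run a configured pipeline
#'
#' Executes simulate / glm / correction / evaluate stages according to the
#' configuration and writes all declared outputs (labeling NIfTIs, a JSON
#' report echoing parameters and seeds, per-stage timings to stderr).
#'
#' Configuration fields: either `simulate` (a list of [synthetic_config()]
#' arguments, with `regions` optionally a [sphere_layout()] name) or `data` +
#' `design` + `contrast` paths; optional `mask` path; `procedures` (subset of
#' uncorrected/fdr/topofdr/gdss/tfce); procedure parameters `alpha`, `q`,
#' `cdt`, `n_perm`, `gamma`; `seed`; `out` (output directory).
#'
#' @param config a named list, or the path of a JSON config file.
#' @return The report list, invisibly; all outputs are written under
#'   `config$out`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$out)) stop("config$out (output directory) is required")
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  procedures <- config$procedures %||% c("uncorrected", "fdr", "gdss")
  timings <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    message(sprintf("[%s] %.1fs", name, timings[[name]]))
    val
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    if (is.character(sim$regions))
      sim$regions <- sphere_layout(sim$regions,
                                   sim$grid_dims %||% c(100L, 100L, 100L))
    sim$seed <- sim$seed %||% seed
    cfg <- do.call(synthetic_config, sim)
    dataset <- tick("simulate", simulate_cohort(cfg))
    truth <- dataset$truth_mask
    covariate <- dataset$ages
  } else {
    if (is.null(config$data) || is.null(config$design))
      stop("config needs either `simulate` or `data` + `design`")
    arr <- tick("read", read_volume(config$data))
    design <- read_design(config$design, dim(arr)[4])
    if (is.null(config$contrast)) stop("config$contrast is required")
    covariate <- design[[config$contrast]]
    dataset <- structure(list(data = arr, ages = covariate,
                              truth_mask = array(FALSE, dim(arr)[1:3]),
                              config = NULL),
                         class = "synthetic_dataset")
    if (!is.null(config$truth)) truth <- read_volume(config$truth) > 0
  }
  mask <- NULL
  if (!is.null(config$mask)) {
    mask <- read_volume(config$mask) > 0
    if (!identical(dim(mask), dim(dataset$data)[1:3]))
      stop(sprintf("mask shape (%s) does not match data shape (%s)",
                   paste(dim(mask), collapse = ","),
                   paste(dim(dataset$data)[1:3], collapse = ",")))
  }

  mrf <- mrf_config(gamma = config$gamma %||% 0.5)
  labs <- tick("procedures", run_procedures(
    dataset, procedures,
    alpha = config$alpha %||% 0.05, q = config$q %||% 0.05,
    cdt = config$cdt %||% 3.0, n_perm = config$n_perm %||% 100L,
    seed = seed + 1000L, mrf = mrf))

  for (nm in names(labs)) {
    lab <- labs[[nm]]$labels
    lab[is.na(lab)] <- 0L
    write_volume(lab, file.path(config$out, paste0(nm, "_labels.nii.gz")))
  }

  report <- list(
    schema_version = 1L,
    package_version = as.character(utils::packageVersion("gdss")),
    seed = seed,
    parameters = config[setdiff(names(config), "out")],
    rejected = lapply(labs, n_rejected))
  if (!is.null(truth) && any(truth)) {
    report$evaluation <- lapply(labs, function(l) {
      s <- score_labeling(l, truth, labs$uncorrected)
      list(tpr = s$tpr, fpr = s$fpr, fpr_rel = s$fpr_rel,
           tp = s$tp, fp = s$fp, fn = s$fn, tn = s$tn)
    })
  }
  jsonlite::write_json(report, file.path(config$out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  message(sprintf("outputs written to %s", config$out))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_cli_args <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument: %s", a))
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[[i + 1]], "--")) {
      out[[key]] <- TRUE
      i <- i + 1
    } else {
      val <- args[[i + 1]]
      num <- suppressWarnings(as.numeric(val))
      out[[key]] <- if (!is.na(num)) num else val
      i <- i + 2
    }
  }
  out
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `glm`, `gdss`, `fdr`, `topofdr`, `tfce`,
#' `evaluate`, `benchmark`, `pipeline`.  Invoke through the installed
#' `exec/gdss` script or as
#' `Rscript -e 'gdss::gdss_cli()' -- <subcommand> --flag value ...`.
#'
#' @param args character vector of arguments (default: the command line).
#' @return Exit status 0 on success, invisibly.
#' @export
gdss_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: gdss <simulate|glm|gdss|fdr|topofdr|tfce|evaluate|benchmark|pipeline> [--flag value ...]")
    return(invisible(1L))
  }
  cmd <- args[[1]]
  opt <- parse_cli_args(args[-1])
  need <- function(field) {
    if (is.null(opt[[field]]))
      stop(sprintf("--%s is required for `%s`", gsub("_", "-", field), cmd))
    opt[[field]]
  }
  outdir <- function() {
    d <- need("out")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  }

  switch(cmd,
    simulate = {
      grid <- rep(as.integer(opt$grid %||% 100), 3)
      cfg <- synthetic_config(
        grid_dims = grid,
        n_subjects = as.integer(opt$n_subjects %||% 50),
        beta1 = opt$beta1 %||% 0,
        regions = sphere_layout(opt$regions %||% "null", grid),
        fwhm = opt$fwhm %||% 4,
        seed = as.integer(opt$seed %||% 1))
      write_dataset(simulate_cohort(cfg), outdir())
    },
    glm = {
      arr <- read_volume(need("data"))
      design <- read_design(need("design"), dim(arr)[4])
      stat <- fit_voxelwise_glm(arr, design, contrast = need("contrast"))
      d <- outdir()
      write_volume(stat$values, file.path(d, "tstat.nii.gz"))
      write_volume(one_sided_p(stat)$values, file.path(d, "pvalue.nii.gz"))
      write_volume(cohens_d(stat), file.path(d, "cohens_d.nii.gz"))
    },
    gdss = {
      arr <- read_volume(need("stat"))
      mask <- if (!is.null(opt$mask)) read_volume(opt$mask) > 0 else NULL
      stat <- statistic_volume(arr, mask, df = as.integer(need("df")), "t")
      grid <- threshold_grid(seq(2.0, 6.5, by = opt$u_step %||% 0.1))
      res <- gdss(stat, grid = grid,
                  mrf = mrf_config(gamma = opt$gamma %||% 0.5))
      d <- outdir()
      lab <- res$labeling$labels
      lab[is.na(lab)] <- 0L
      write_volume(lab, file.path(d, "gdss_labels.nii.gz"))
      jsonlite::write_json(res$report, file.path(d, "gdss_report.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    fdr = {
      arr <- read_volume(need("p"))
      p <- p_value_volume(arr)
      lab <- fdr_labeling(p, q = opt$q %||% 0.05,
                          c_form = opt$variant %||% "by")
      d <- outdir()
      write_volume(lab$labels, file.path(d, "fdr_labels.nii.gz"))
    },
    topofdr = {
      arr <- read_volume(need("stat"))
      stat <- statistic_volume(arr, df = as.integer(need("df")), kind = "t")
      lab <- topological_fdr(stat, cdt = opt$cdt %||% 3.0,
                             q = opt$q %||% 0.05)
      d <- outdir()
      write_volume(lab$labels, file.path(d, "topofdr_labels.nii.gz"))
      write.csv(attr(lab, "clusters"), file.path(d, "clusters.csv"),
                row.names = FALSE)
    },
    tfce = {
      arr <- read_volume(need("data"))
      design <- read_design(need("design"), dim(arr)[4])
      lab <- tfce_permutation_test(
        arr, covariate = design[[need("contrast")]],
        n_perm = as.integer(opt$n_perm %||% 100),
        alpha = opt$alpha %||% 0.05, seed = as.integer(opt$seed %||% 1))
      d <- outdir()
      write_volume(lab$labels, file.path(d, "tfce_labels.nii.gz"))
    },
    evaluate = {
      lab <- labeling_from_mask(read_volume(need("labeling")) > 0)
      truth <- read_volume(need("truth")) > 0
      unc <- if (!is.null(opt$uncorrected))
        labeling_from_mask(read_volume(opt$uncorrected) > 0) else NULL
      s <- score_labeling(lab, truth, unc)
      jsonlite::write_json(
        list(tpr = s$tpr, fpr = s$fpr, fpr_rel = s$fpr_rel, tp = s$tp,
             fp = s$fp, fn = s$fn, tn = s$tn),
        file.path(outdir(), "evaluation.json"),
        auto_unbox = TRUE, digits = NA)
    },
    benchmark = {
      grid <- rep(as.integer(opt$grid %||% 40), 3)
      cfg <- synthetic_config(grid_dims = grid,
                              n_subjects = as.integer(opt$n_subjects %||% 50),
                              fwhm = opt$fwhm %||% 4,
                              seed = as.integer(opt$seed %||% 1))
      res <- null_benchmark(as.integer(opt$n_datasets %||% 10), cfg,
                            n_perm = as.integer(opt$n_perm %||% 100),
                            progress = TRUE)
      jsonlite::write_json(
        list(fwer = as.list(res$fwer),
             avg_significant = as.list(res$avg_significant),
             counts = res$counts),
        file.path(outdir(), "benchmark.json"),
        auto_unbox = TRUE, digits = NA)
    },
    pipeline = run_pipeline(need("config")),
    stop(sprintf("unknown subcommand: %s", cmd))
  )
  invisible(0L)
}
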