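#' Read a numeric matrix (data or covariance) from delimited text
#'
#' Accepts comma- or tab-delimited files, with or without a header row of
#' variable names; the delimiter is sniffed from the first line.
#'
#' @param path file path.
#' @param header force header handling; `NA` (default) auto-detects by
#'   checking whether the first row parses as numbers.
#' @return numeric matrix (with column names when a header is present).
#' @export
read_matrix_txt <- function(path, header = NA) {
  if (!file.exists(path)) stop("input file not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  if (is.na(header)) {
    fields <- strsplit(first, sep, fixed = TRUE)[[1]]
    header <- any(is.na(suppressWarnings(as.numeric(fields))))
  }
  df <- utils::read.table(path, header = header, sep = sep,
                          check.names = FALSE)
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad))
    stop("non-numeric values in column(s): ",
         paste(names(df)[bad], collapse = ", "))
  as.matrix(df)
}

#' Write a numeric matrix as delimited text at full double precision
#'
#' Values are written with 17 significant digits so a write-then-read
#' round trip is lossless.
#'
#' @param x numeric matrix.
#' @param path output file path.
#' @param col_names include a header row?
#' @export
write_matrix_txt <- function(x, path, col_names = !is.null(colnames(x))) {
  x <- as.matrix(x)
  ch <- matrix(formatC(x, digits = 17, format = "g"), nrow(x), ncol(x))
  lines <- apply(ch, 1, paste, collapse = ",")
  if (col_names && !is.null(colnames(x)))
    lines <- c(paste(colnames(x), collapse = ","), lines)
  writeLines(lines, path)
}

structure_to_list <- function(st) {
  lapply(stats::setNames(st$clusters, paste0("group_", seq_len(st$G))),
         as.integer)
}

#' Write a fit result record to a directory
#'
#' Writes the estimated loadings, factor correlation matrix and
#' uniquenesses as delimited text at full precision, the estimated
#' structure as JSON (1-based variable indices), and a `result.json`
#' metadata record (loss, BIC, convergence diagnostics, configuration
#' echo, package version, seed).
#'
#' @param fit a `bifactor_fit` object from [fit_multistart()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fit_result <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_txt(fit$params$loadings, file.path(dir, "loadings.csv"))
  write_matrix_txt(build_phi(fit$params$beta, fit$params$G),
                   file.path(dir, "phi.csv"))
  write_matrix_txt(matrix(fit$params$psi, ncol = 1),
                   file.path(dir, "psi.csv"))
  st <- fit$structure %||%
    extract_structure(fit$params$loadings, fit$config$eps_struct)
  jsonlite::write_json(structure_to_list(st),
                       file.path(dir, "structure.json"))
  meta <- list(
    loss = fit$loss,
    bic = bic_bifactor(fit$loss, fit$N, fit$G),
    G = fit$G, J = fit$params$J, N = fit$N,
    converged = fit$converged,
    is_correlation = fit$is_correlation,
    n_starts = fit$n_starts_used %||% 1L,
    n_converged_starts = sum(fit$start_converged %||% fit$converged),
    winning_start = fit$winning_start %||% 1L,
    restarts_used = fit$restarts_used,
    runtime_sec = fit$elapsed %||% NA_real_,
    seed = fit$config$seed,
    config = fit$config[c("mu0", "rho", "gamma", "mu_max", "max_outer",
                          "max_restarts", "eps_param", "eps_struct",
                          "inner_tol", "constraint_form", "profile")],
    version = as.character(utils::packageVersion("ebifactor")))
  jsonlite::write_json(meta, file.path(dir, "result.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Fit workflow: delimited input to result directory
#'
#' Loads a dataset (`kind = "data"`, computing the sample covariance) or a
#' covariance/correlation matrix, fits the exact bi-factor model with `G`
#' group factors by [fit_multistart()], canonicalizes the solution, and
#' writes the result record.
#'
#' @param input path to a delimited text file.
#' @param kind `"data"` (N x J observations), `"covariance"`, or
#'   `"correlation"`.
#' @param G number of group factors.
#' @param out_dir output directory.
#' @param N sample size (required for covariance/correlation input).
#' @param config an [alm_config()] object.
#' @param denominator covariance denominator for raw-data input.
#' @return the `bifactor_fit`, invisibly; results on disk in `out_dir`.
#' @export
run_fit <- function(input, kind = c("data", "covariance", "correlation"),
                    G, out_dir, N = NULL, config = alm_config(),
                    denominator = "N") {
  kind <- match.arg(kind)
  x <- read_matrix_txt(input)
  sample <- load_sample(x, kind, N, denominator)
  fit <- fit_multistart(sample, G, config)
  write_fit_result(fit, out_dir)
  invisible(fit)
}

load_sample <- function(x, kind, N, denominator = "N") {
  if (kind == "data") {
    compute_sample_cov(x, denominator)
  } else {
    if (is.null(N))
      stop("N must be supplied with covariance/correlation input")
    sample_covariance(x, N, is_correlation = kind == "correlation")
  }
}

#' Selection workflow: delimited input to selection table
#'
#' Runs [select_num_groups()] over a candidate range and writes the
#' selection table (`candidate_G, loss, penalty, BIC, converged_starts`)
#' as CSV plus the winning fit's result record.
#'
#' @inheritParams run_fit
#' @param candidates integer vector of candidate `G` values.
#' @return the `ebifa_selection`, invisibly.
#' @export
run_select <- function(input, kind = c("data", "covariance", "correlation"),
                       candidates, out_dir, N = NULL,
                       config = alm_config(), denominator = "N") {
  kind <- match.arg(kind)
  x <- read_matrix_txt(input)
  sample <- load_sample(x, kind, N, denominator)
  sel <- select_num_groups(sample, candidates, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- data.frame(
    candidate_G = sel$candidate_G,
    loss = sel$loss_values,
    penalty = (sel$candidate_G * (sel$candidate_G - 1) / 2) * log(sel$N),
    bic = sel$bic_values,
    converged_starts = vapply(sel$fits, function(f)
      if (inherits(f, "bifactor_fit")) sum(f$start_converged) else 0L,
      integer(1)))
  utils::write.csv(tab, file.path(out_dir, "selection.csv"),
                   row.names = FALSE)
  best <- sel$fits[[match(sel$chosen_G, sel$candidate_G)]]
  write_fit_result(best, file.path(out_dir, "best_fit"))
  invisible(sel)
}

#' Simulation workflow: scenario file to datasets and truth records
#'
#' Reads a YAML scenario describing a [simulation_design()], a replication
#' count, and whether the model is exact or approximate; generates the
#' population model once (fixed model seed) and then one dataset per
#' replication varying only the data seed; writes each dataset and sample
#' covariance as CSV with a JSON truth sidecar.
#'
#' Scenario fields: `J, G, N, model` (`"exact"`/`"approx"`),
#' `replications`, `model_seed`, `data_seed_base`, and optional overrides
#' of the generator ranges (`general_range`, `group_range`, `sign_prob`,
#' `perturb_range`, `beta_range`, `psi_value`).
#'
#' @param scenario path to a YAML scenario file.
#' @param out_dir output directory.
#' @return the `ground_truth`, invisibly.
#' @export
run_simulate <- function(scenario, out_dir) {
  # keep YAML 1.1 boolean-like keys such as "N" as literal strings
  sc <- yaml::read_yaml(scenario,
                        handlers = list("bool#yes" = function(x) x,
                                        "bool#no" = function(x) x))
  required <- c("J", "G", "N", "model", "replications")
  missing <- setdiff(required, names(sc))
  if (length(missing))
    stop("scenario is missing field(s): ", paste(missing, collapse = ", "))
  if (!sc$model %in% c("exact", "approx"))
    stop("scenario field 'model' must be \"exact\" or \"approx\"")
  design <- simulation_design(
    J = sc$J, G = sc$G, N = sc$N,
    clusters = sc$clusters %||% "equal_blocks",
    general_range = unlist(sc$general_range %||% c(0.5, 1.5)),
    group_range = unlist(sc$group_range %||% c(0.5, 1.5)),
    sign_prob = sc$sign_prob %||% 0.5,
    perturb_range = unlist(sc$perturb_range %||% c(0, 0.1)),
    beta_range = unlist(sc$beta_range %||% c(-1, 1)),
    psi_value = sc$psi_value %||% 1,
    seed = sc$model_seed %||% 1L)
  truth <- if (sc$model == "exact") generate_exact_model(design)
  else generate_approx_model(design)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- sc$data_seed_base %||% 1000L
  for (r in seq_len(sc$replications)) {
    ds <- sample_dataset(truth, N = sc$N, seed = child_seed(base, r))
    write_matrix_txt(ds$data, file.path(out_dir,
                                        sprintf("data_%03d.csv", r)))
    write_matrix_txt(ds$sample$S, file.path(out_dir,
                                            sprintf("cov_%03d.csv", r)))
    jsonlite::write_json(
      list(replicate = r, seed = child_seed(base, r), N = sc$N,
           G = design$G, J = design$J, is_exact = truth$is_exact,
           loadings = truth$params$loadings,
           beta = truth$params$beta, psi = truth$params$psi,
           clusters = structure_to_list(truth$structure)),
      file.path(out_dir, sprintf("truth_%03d.json", r)),
      digits = NA)
  }
  invisible(truth)
}

read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  list(params = bifactor_params(tr$loadings, tr$beta, tr$psi),
       structure = bifactor_structure(tr$clusters, nrow(tr$loadings)),
       G = tr$G, replicate = tr$replicate)
}

#' Evaluation workflow: fitted results against truth records
#'
#' Matches `fit_***` result directories against `truth_***.json` sidecars
#' by replicate id, computes the loading MSE, EMC, ACC and SC per
#' replicate, and writes a metrics table with summary means. Unmatched
#' replicate ids are listed and skipped with a warning.
#'
#' @param results_dir directory containing per-replicate fit directories
#'   named `fit_<id>`.
#' @param truth_dir directory containing `truth_<id>.json` files.
#' @param out output CSV path.
#' @return the metrics data frame, invisibly.
#' @export
run_evaluate <- function(results_dir, truth_dir,
                         out = file.path(results_dir, "metrics.csv")) {
  fit_dirs <- list.dirs(results_dir, recursive = FALSE)
  fit_dirs <- fit_dirs[grepl("fit_[0-9]+$", fit_dirs)]
  fit_ids <- as.integer(sub(".*fit_", "", fit_dirs))
  truth_files <- list.files(truth_dir, pattern = "^truth_[0-9]+\\.json$",
                            full.names = TRUE)
  truth_ids <- as.integer(gsub("\\D", "", basename(truth_files)))
  common <- intersect(fit_ids, truth_ids)
  orphan <- c(setdiff(fit_ids, truth_ids), setdiff(truth_ids, fit_ids))
  if (length(orphan))
    warning("unmatched replicate id(s) skipped: ",
            paste(sort(orphan), collapse = ", "))
  rows <- lapply(sort(common), function(id) {
    tr <- read_truth(truth_files[match(id, truth_ids)])
    dir <- fit_dirs[match(id, fit_ids)]
    est_loadings <- read_matrix_txt(file.path(dir, "loadings.csv"))
    meta <- jsonlite::read_json(file.path(dir, "result.json"),
                                simplifyVector = TRUE)
    est_clusters <- jsonlite::read_json(file.path(dir, "structure.json"),
                                        simplifyVector = TRUE)
    est_st <- bifactor_structure(est_clusters, nrow(est_loadings))
    same_g <- est_st$G == tr$structure$G
    data.frame(replicate = id,
               seed = meta$seed %||% NA_integer_,
               mse = if (same_g)
                 loading_mse(tr$params$loadings, est_loadings) else NA_real_,
               emc = if (same_g) emc(tr$structure, est_st) else 0,
               acc = if (same_g) acc(tr$structure, est_st)$value else NA_real_,
               sc = selection_correctness(meta$G, tr$G),
               converged = meta$converged,
               runtime_sec = meta$runtime_sec %||% NA_real_)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, out, row.names = FALSE)
  invisible(tab)
}
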