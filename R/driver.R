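# Fixed priority for breaking exact C-score ties: log is the field-standard
# default preprocessing, so it wins ties, then zscore, none, sctransform.
METHOD_PRIORITY <- c("log", "zscore", "none", "sctransform")

#' Run the full preprocessing-selection pipeline
#'
#' For each candidate preprocessing method and each repeat `r = 1..N`, the
#' expression matrix is transformed, gene-filtered, consensus-clustered and
#' graph-scored, with the repeat's seed derived deterministically from
#' `(master_seed, method, r)` so the ensemble of one method never perturbs
#' another's. Per-method C-scores are averaged over the `N` repeats and the
#' method with the smallest mean C-score is selected (ties broken by the
#' fixed priority log > zscore > none > sctransform). A method whose engine
#' errors is marked failed and excluded from the selection. The consensus
#' clustering is stochastic, so `N > 1` (the repeat average) buys stability
#' at proportional cost; `N = 1` is the default.
#'
#' @param M an [ExpressionMatrix].
#' @param k number of clusters to cut the consensus into (required; no
#'   k-estimation is performed).
#' @param methods subset of `"log"`, `"zscore"`, `"none"`, `"sctransform"`.
#' @param N repeat count per method (>= 1).
#' @param params a [GraphParams] (alpha/beta thresholds).
#' @param master_seed integer seed for the whole run.
#' @param truth optional ground-truth labels ([ClusterLabels] or vector) for
#'   per-method ARI reporting.
#' @param max_cells cap on the number of cells; larger inputs are
#'   subsampled first (seeded from `master_seed`).
#' @param d_range,filter,lower_pct,upper_pct consensus-engine settings, see
#'   [sc3_consensus()].
#' @return an object of class `SelectionReport`: per-method score tables,
#'   mean C-scores, labels and consensus of the final repeat, optional ARI,
#'   the selected method, and a `zero_score_warning` flag (set when any
#'   surviving method's mean C-score is exactly 0, in which case the scores
#'   may not discriminate the methods).
#' @export
run_sc3e <- function(M, k, methods = METHOD_PRIORITY, N = 1L,
                     params = GraphParams(), master_seed = 1L,
                     truth = NULL, max_cells = 5000L,
                     d_range = c(0.04, 0.07), filter = TRUE,
                     lower_pct = 0.06, upper_pct = 0.94) {
  stopifnot(inherits(M, "ExpressionMatrix"), inherits(params, "GraphParams"))
  methods <- match.arg(methods, METHOD_PRIORITY, several.ok = TRUE)
  if (length(methods) == 0L) stopf("'methods' must be non-empty")
  k <- check_count(k, "k", min = 2L)
  N <- check_count(N, "N", min = 1L)
  if (ncol(M$values) <= k)
    stopf("need more cells (%d) than clusters (%d)", ncol(M$values), k)

  M <- subsample_cells(M, max_cells, seed = stable_seed(master_seed, "subsample"))
  truth_vec <- if (is.null(truth)) NULL else as_label_vector(truth)
  if (!is.null(truth_vec) && length(truth_vec) != ncol(M$values))
    stopf("truth labels cover %d cells, matrix has %d",
          length(truth_vec), ncol(M$values))

  timings <- list()
  results <- list()
  for (method in methods) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      P <- preprocess(M, method)
      scores <- data.frame(repeat_index = seq_len(N), W_in = NA_real_,
                           D_out = NA_real_, c_score = NA_real_,
                           zero_score = NA)
      last <- NULL
      for (r in seq_len(N)) {
        run <- sc3_consensus(P, k,
                             seed = stable_seed(master_seed, method, r),
                             d_range = d_range, filter = filter,
                             lower_pct = lower_pct, upper_pct = upper_pct)
        cs <- consensus_c_score(run$consensus, run$labels, params)
        scores[r, c("W_in", "D_out", "c_score")] <-
          c(cs$W_in, cs$D_out, cs$c_score)
        scores$zero_score[r] <- cs$zero_score
        last <- run
      }
      list(status = "ok",
           scores = scores,
           mean_c_score = mean(scores$c_score),
           labels = last$labels,
           consensus = last$consensus,
           ari = if (is.null(truth_vec)) NA_real_ else
             adjusted_rand_index(last$labels, truth_vec))
    }, error = function(e) {
      list(status = "failed", message = conditionMessage(e),
           mean_c_score = NA_real_)
    })
    timings[[method]] <- proc.time()[["elapsed"]] - t0
    results[[method]] <- res
  }

  report <- structure(list(
    methods = methods,
    k = k, N = N,
    alpha = params$alpha, beta = params$beta,
    master_seed = as.integer(master_seed),
    n_cells = ncol(M$values),
    n_genes = nrow(M$values),
    results = results,
    mean_c_scores = vapply(results, function(r) r$mean_c_score, numeric(1)),
    timings = unlist(timings),
    selected_method = NA_character_,
    zero_score_warning = FALSE
  ), class = "SelectionReport")

  ok <- vapply(results, function(r) r$status == "ok", logical(1))
  if (!any(ok)) stopf("every preprocessing method failed")
  report$zero_score_warning <- any(report$mean_c_scores[ok] == 0)
  report$selected_method <- select_best(report)
  report
}

#' Pick the method with the smallest mean C-score
#'
#' Argmin of the per-method mean C-scores over the non-failed methods;
#' exact ties go to the earliest method in the fixed priority order
#' log > zscore > none > sctransform.
#'
#' @param report a `SelectionReport` from [run_sc3e()].
#' @return the selected method name.
#' @export
select_best <- function(report) {
  stopifnot(inherits(report, "SelectionReport"))
  ok <- vapply(report$results, function(r) r$status == "ok", logical(1))
  if (!any(ok)) stopf("every preprocessing method failed")
  scores <- report$mean_c_scores[ok]
  candidates <- names(scores)[scores == min(scores)]
  METHOD_PRIORITY[METHOD_PRIORITY %in% candidates][1L]
}

#' @export
print.SelectionReport <- function(x, ...) {
  cat(sprintf("SelectionReport: %d cells, %d genes, k = %d, N = %d, alpha = %g, beta = %g\n",
              x$n_cells, x$n_genes, x$k, x$N, x$alpha, x$beta))
  for (m in x$methods) {
    r <- x$results[[m]]
    if (r$status == "ok") {
      cat(sprintf("  %-12s mean C-score = %-12.6g%s%s\n", m, r$mean_c_score,
                  if (!is.na(r$ari)) sprintf(" ARI = %.4f", r$ari) else "",
                  if (m == x$selected_method) "  <- selected" else ""))
    } else {
      cat(sprintf("  %-12s FAILED: %s\n", m, r$message))
    }
  }
  if (x$zero_score_warning)
    cat("  warning: a mean C-score is exactly 0; methods may be indistinguishable\n")
  invisible(x)
}

report_to_list <- function(report) {
  res <- lapply(report$results, function(r) {
    if (r$status != "ok")
      return(list(status = r$status, message = r$message))
    list(status = r$status,
         scores = r$scores[, c("repeat_index", "W_in", "D_out", "c_score",
                               "zero_score")],
         mean_c_score = r$mean_c_score,
         ari = if (is.na(r$ari)) NULL else r$ari,
         labels = r$labels$labels)
  })
  list(methods = report$methods, k = report$k, N = report$N,
       alpha = report$alpha, beta = report$beta,
       master_seed = report$master_seed,
       n_cells = report$n_cells, n_genes = report$n_genes,
       mean_c_scores = as.list(report$mean_c_scores),
       selected_method = report$selected_method,
       zero_score_warning = report$zero_score_warning,
       results = res)
}

#' Write a selection report to a directory
#'
#' Writes `report.json` (the full report, deterministic byte-for-byte for a
#' fixed input and master seed), `labels_<method>.tsv` and
#' `consensus_<method>.tsv` for every successful method, and `run.log` with
#' per-method timings (the log is the only non-deterministic file).
#'
#' @param report a `SelectionReport`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "SelectionReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_to_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", dataframe = "columns")
  for (m in report$methods) {
    r <- report$results[[m]]
    if (r$status != "ok") next
    write_labels(r$labels$labels, file.path(dir, sprintf("labels_%s.tsv", m)))
    write_consensus(r$consensus, file.path(dir, sprintf("consensus_%s.tsv", m)))
  }
  writeLines(c(sprintf("selected_method\t%s", report$selected_method),
               sprintf("timing_seconds\t%s\t%.3f",
                       names(report$timings), report$timings)),
             file.path(dir, "run.log"))
  invisible(dir)
}
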