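#' Random train/test split of proteins
#'
#' Uniform partition with `|training| = round(p * n)` (half away from zero),
#' deterministic given the seed. Degenerate splits (empty training or test
#' set) are an error.
#'
#' @param proteins eligible protein ids.
#' @param p training fraction in (0, 1).
#' @param seed RNG seed.
#' @return List with sorted `train` and `test` id vectors.
#' @export
split_proteins <- function(proteins, p, seed = 1) {
  n <- length(proteins)
  stopifnot(n > 0, p > 0, p < 1)
  ntr <- floor(p * n + 0.5)
  if (ntr == 0 || ntr == n)
    stop("training fraction ", p, " leaves an empty train or test set for n = ",
         n, call. = FALSE)
  .with_seed(seed, {
    train <- sample(proteins, ntr)
    list(train = sort(train), test = sort(setdiff(proteins, train)))
  })
}

#' Ranked relative deviations against a random-pairing null
#'
#' For each protein the relative deviation is
#' `alpha = |estimated - observed| / observed`. The ranked alpha curve is
#' compared with `R` random pairings in which the estimated values are
#' permuted across the proteins, reporting the per-rank null mean and
#' central 95% band.
#'
#' @param estimated,observed named numeric vectors (matched on names).
#' @param R number of null replicates.
#' @param seed RNG seed for the permutations.
#' @return List with `alpha` (per-protein data.frame) and `ranked`
#'   (data.frame rank, alpha, null_mean, null_lo, null_hi).
#' @export
relative_deviation_report <- function(estimated, observed, R = 200,
                                      seed = 1) {
  common <- intersect(names(estimated), names(observed))
  stopifnot(length(common) > 0, all(observed[common] > 0))
  est <- estimated[common]; obs <- observed[common]
  alpha <- abs(est - obs) / obs
  n <- length(common)
  nulls <- .with_seed(seed, {
    vapply(seq_len(R), function(r)
      sort(abs(est[sample(n)] - obs) / obs), numeric(n))
  })
  nulls <- matrix(nulls, nrow = n)
  ranked <- data.frame(
    rank = seq_len(n), alpha = sort(unname(alpha)),
    null_mean = rowMeans(nulls),
    null_lo = apply(nulls, 1, quantile, probs = 0.025, names = FALSE),
    null_hi = apply(nulls, 1, quantile, probs = 0.975, names = FALSE))
  list(alpha = data.frame(protein = common, estimated = unname(est),
                          observed = unname(obs), alpha = unname(alpha),
                          stringsAsFactors = FALSE),
       ranked = ranked)
}

#' Validate abundance estimation by masking known proteins
#'
#' Splits the proteins with known abundance, solves the LP on the training
#' abundances only, imputes the masked test proteins from the solved copy
#' numbers, and reports their ranked relative deviations against the
#' random-pairing null. Test proteins in no determined complex cannot be
#' imputed and are counted out.
#'
#' @param dataset a [complexome_dataset()].
#' @param abundance an [abundance_table()].
#' @param condition condition label.
#' @param p training fraction.
#' @param seed RNG seed (split and null permutations).
#' @param R null replicates.
#' @return Object of class `abundance_validation`: list with the split, the
#'   masked-LP solution, `n_imputable`, and the deviation `report` (possibly
#'   empty, with a warning, if nothing was imputable).
#' @export
validate_abundance <- function(dataset, abundance, condition, p = 0.5,
                               seed = 1, R = 200) {
  known <- condition_abundance(abundance, condition)
  known <- known[known > 0]
  core_prot <- unique(
    dataset$memberships$protein[dataset$memberships$role == "core"])
  eligible <- sort(intersect(names(known), core_prot))
  sp <- split_proteins(eligible, p, seed)
  e <- abundance$entries
  mask <- e$condition == condition & e$protein %in% sp$test
  e$abundance[mask] <- NA
  masked <- abundance_table(e, conditions = abundance$conditions)
  problem <- build_abundance_problem(dataset, masked, condition)
  sol <- solve_abundance(problem)
  imp <- impute_abundance(sol, dataset)
  determined <- names(imp)[attr(imp, "provenance") == "solved"]
  usable <- intersect(sp$test, determined)
  out <- list(train = sp$train, test = sp$test, solution = sol,
              n_imputable = length(usable), condition = condition, p = p)
  if (length(usable) == 0) {
    warning("no test protein sits in a determined complex; empty report",
            call. = FALSE)
    out$report <- NULL
  } else {
    out$report <- relative_deviation_report(imp[usable], known[usable],
                                            R = R, seed = seed + 1L)
  }
  structure(out, class = "abundance_validation")
}

#' @export
print.abundance_validation <- function(x, ...) {
  cat("abundance validation (", x$condition, ", p = ", x$p, "): ",
      length(x$train), " train / ", length(x$test), " test, ",
      x$n_imputable, " imputable\n", sep = "")
  if (!is.null(x$report))
    cat("  median alpha ", signif(median(x$report$alpha$alpha), 4),
        " vs null ", signif(median(x$report$ranked$null_mean), 4), "\n",
        sep = "")
  invisible(x)
}

.fraction_row <- function(outcome, metric, num, den) {
  data.frame(outcome = outcome, metric = metric, numerator = num,
             denominator = den,
             fraction = if (den > 0) num / den else NA_real_,
             stringsAsFactors = FALSE)
}

#' Validate function assignment by masking annotated proteins
#'
#' Splits the annotated proteins, hides the test proteins' annotations, runs
#' the full assignment pipeline (cover solve, HC filter, core-only
#' re-substitution) on the training annotations, and scores the predictions
#' made for test proteins against their held-out annotations:
#'
#' * fraction of functions: predicted (protein, function) pairs present in
#'   the held-out truth, over all predicted pairs on test proteins;
#' * fraction of proteins: test proteins with at least one correct predicted
#'   function, over test proteins with at least one prediction.
#'
#' Both are reported for the raw outcome and the HC subset, with their
#' numerator/denominator counts (`NA` fraction when nothing was predicted).
#'
#' @param dataset a [complexome_dataset()].
#' @param functions a [function_table()] of known annotations.
#' @param p training fraction.
#' @param seed RNG seed for the split.
#' @param variant cover objective, see [solve_function_assignment()].
#' @return Object of class `function_validation`: the split, the solved
#'   (HC-labelled) `solution`, the `predictions` for test proteins (raw and
#'   HC), and the `metrics` table.
#' @export
validate_functions <- function(dataset, functions, p = 0.5, seed = 1,
                               variant = c("min_complexes",
                                           "min_proteins")) {
  variant <- match.arg(variant)
  eligible <- sort(intersect(names(functions$entries), dataset$proteins))
  sp <- split_proteins(eligible, p, seed)
  masked <- function_table(functions$entries[sp$train])
  problem <- build_function_problem(dataset, masked)
  sol <- hc_filter(problem, solve_function_assignment(problem, variant))
  pred <- list(
    raw = resubstitute_protein_functions(sol, dataset, masked,
                                         hc_only = FALSE),
    HC = resubstitute_protein_functions(sol, dataset, masked,
                                        hc_only = TRUE))
  truth <- functions$entries
  metrics <- do.call(rbind, lapply(names(pred), function(lvl) {
    pr <- pred[[lvl]]
    pr <- pr[pr$protein %in% sp$test, , drop = FALSE]
    correct <- mapply(function(i, k) k %in% truth[[i]], pr$protein, pr$code)
    correct <- as.logical(correct)
    with_pred <- unique(pr$protein)
    with_correct <- unique(pr$protein[correct])
    rbind(.fraction_row(lvl, "fraction_of_functions",
                        sum(correct), nrow(pr)),
          .fraction_row(lvl, "fraction_of_proteins",
                        length(with_correct), length(with_pred)))
  }))
  structure(list(train = sp$train, test = sp$test, solution = sol,
                 predictions = pred, metrics = metrics, p = p,
                 variant = variant),
            class = "function_validation")
}

#' @export
print.function_validation <- function(x, ...) {
  cat("function validation (", x$variant, ", p = ", x$p, "): ",
      length(x$train), " train / ", length(x$test), " test\n", sep = "")
  m <- x$metrics
  for (r in seq_len(nrow(m)))
    cat(sprintf("  %-21s %-4s %s\n", m$metric[r], m$outcome[r],
                if (is.na(m$fraction[r]))
                  sprintf("undefined (%d/%d)", m$numerator[r],
                          m$denominator[r])
                else sprintf("%.1f%% (%d/%d)", 100 * m$fraction[r],
                             m$numerator[r], m$denominator[r])))
  invisible(x)
}
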