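#' Build an abundance estimation problem
#'
#' Complex copy numbers are estimated from core memberships only: core
#' proteins form each complex's skeleton, whereas attachment proteins are
#' shared promiscuously and would overestimate copy numbers. The
#' stoichiometric matrix `S` holds the membership copies (default 1, i.e.
#' the binary-membership approximation). Proteins with unknown or zero
#' abundance in the chosen condition are kept in `S`'s row space (so they
#' can be imputed later) but impose no constraint and do not enter the
#' objective.
#'
#' @param dataset a [complexome_dataset()].
#' @param abundance an [abundance_table()].
#' @param condition condition label (e.g. `"YEPD"` or `"SD"`).
#' @return Object of class `abundance_problem`: list with sparse `S`
#'   (protein x complex, core copies), known positive abundances `p` over
#'   the constraint set `K`, and the `condition`.
#' @export
build_abundance_problem <- function(dataset, abundance, condition) {
  core <- dataset$memberships[dataset$memberships$role == "core", ,
                              drop = FALSE]
  if (nrow(core) == 0)
    stop("nothing to estimate: the dataset has no core memberships",
         call. = FALSE)
  proteins <- sort(unique(core$protein))
  complexes <- sort(unique(core$complex))
  S <- Matrix::sparseMatrix(i = match(core$protein, proteins),
                            j = match(core$complex, complexes),
                            x = core$copies,
                            dims = c(length(proteins), length(complexes)),
                            dimnames = list(proteins, complexes))
  p_all <- condition_abundance(abundance, condition)
  p <- p_all[names(p_all) %in% proteins & p_all > 0]
  structure(list(S = S, p = p, K = names(p), proteins = proteins,
                 complexes = complexes, condition = condition,
                 all_complexes = dataset$complexes),
            class = "abundance_problem")
}

#' Estimate complex copy numbers by linear programming
#'
#' In the ideal balance every protein's abundance equals the amount consumed
#' by complex formation, `p_i = sum_j S_ij c_j`. That linear system is
#' over-determined, so instead the availability constraint
#' `sum_j S_ij c_j <= p_i` is imposed for every protein with known positive
#' abundance and the total leftover
#' `DA = sum_{i in K} (p_i - sum_j S_ij c_j)` is minimized over `c >= 0`
#' (equivalently, the consumed abundance is maximized). Complexes with no
#' core member in the constraint set are undetermined: they are assigned
#' `c = 0` and flagged.
#'
#' @param problem an [build_abundance_problem()] result.
#' @param intervals logical; also compute, per determined complex, the
#'   `[min, max]` of its copy number over the optimal face (degenerate
#'   optima are common in set-like LPs), by lexicographic re-optimization.
#' @return Object of class `abundance_solution`: list with copy numbers `c`
#'   (named, all complexes of the problem), objective `DA`, per-protein
#'   `slack`, `undetermined` complex ids, and optionally `intervals`.
#' @export
#' @examples
#' ds <- complexome_dataset(data.frame(complex = "J", protein = c("x", "y"),
#'                                     role = "core"))
#' ab <- abundance_table(data.frame(protein = c("x", "y"), condition = "YEPD",
#'                                  abundance = c(5, 3)))
#' sol <- solve_abundance(build_abundance_problem(ds, ab, "YEPD"))
#' sol$c    # J = 3 (bound by the scarcer core protein)
#' sol$DA   # 2
solve_abundance <- function(problem, intervals = FALSE) {
  stopifnot(inherits(problem, "abundance_problem"))
  S <- problem$S
  K <- problem$K
  SK <- S[K, , drop = FALSE]
  w <- Matrix::colSums(SK)
  det_cols <- which(w > 0)
  undetermined <- colnames(S)[w == 0]
  cvec <- setNames(numeric(ncol(S)), colnames(S))
  value <- 0
  if (length(det_cols) > 0) {
    A <- as.matrix(SK[, det_cols, drop = FALSE])
    rows <- which(rowSums(A) > 0)
    A <- A[rows, , drop = FALSE]
    b <- unname(problem$p[rows])
    obj <- unname(w[det_cols])
    fit <- lp_max(A, b, obj)
    cvec[det_cols] <- fit$x
    value <- fit$value
  }
  slack <- as.numeric(problem$p - (SK %*% cvec)[, 1][K])
  names(slack) <- K
  DA <- sum(problem$p) - value
  sol <- structure(list(c = cvec, DA = DA, slack = slack,
                        undetermined = undetermined,
                        condition = problem$condition, K = K,
                        objective = "L1 leftover under availability"),
                   class = "abundance_solution")
  if (intervals && length(det_cols) > 0) {
    A <- as.matrix(SK[, det_cols, drop = FALSE])
    rows <- which(rowSums(A) > 0)
    A <- A[rows, , drop = FALSE]
    b <- unname(problem$p[rows])
    obj <- unname(w[det_cols])
    # lexicographic (coverage first, then +/- c_j) via a large multiplier
    bigM <- 1e6 * max(1, max(b))
    iv <- t(vapply(seq_along(det_cols), function(jj) {
      ej <- replace(numeric(length(det_cols)), jj, 1)
      hi <- lp_max(A, b, bigM * obj + ej)$x[jj]
      lo <- lp_max(A, b, bigM * obj - ej)$x[jj]
      c(lo, hi)
    }, numeric(2)))
    sol$intervals <- data.frame(complex = colnames(S)[det_cols],
                                min = iv[, 1], max = iv[, 2],
                                stringsAsFactors = FALSE)
  }
  sol
}

#' @export
print.abundance_solution <- function(x, ...) {
  cat("abundance solution (", x$condition, "): ", length(x$c),
      " complexes, DA = ", signif(x$DA, 6), ", ",
      length(x$undetermined), " undetermined\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.abundance_solution <- function(x, ...) {
  data.frame(complex = names(x$c), copy_number = unname(x$c),
             undetermined = names(x$c) %in% x$undetermined,
             stringsAsFactors = FALSE)
}

#' Impute unknown protein abundances from solved copy numbers
#'
#' For proteins outside the constraint set (unknown or zero measured
#' abundance) the ideal balance is applied with the solved copy numbers:
#' `p_hat_i = sum_j S_ij c_j` over the protein's core memberships. Proteins
#' whose core complexes are all undetermined get 0 with an `"undetermined"`
#' provenance flag; proteins with no core membership are not imputed.
#'
#' @param solution an [solve_abundance()] result.
#' @param dataset the [complexome_dataset()] the problem was built from.
#' @return Named numeric vector of imputed abundances with a `provenance`
#'   attribute (`"solved"` or `"undetermined"` per protein).
#' @export
impute_abundance <- function(solution, dataset) {
  core <- dataset$memberships[dataset$memberships$role == "core", ,
                              drop = FALSE]
  targets <- setdiff(sort(unique(core$protein)), solution$K)
  if (length(targets) == 0)
    return(structure(numeric(0), provenance = character(0)))
  core <- core[core$protein %in% targets, , drop = FALSE]
  cvals <- solution$c[core$complex]
  est <- tapply(core$copies * cvals, core$protein, sum)
  det <- tapply(!core$complex %in% solution$undetermined, core$protein, any)
  out <- setNames(as.numeric(est), names(est))[targets]
  structure(out,
            provenance = setNames(ifelse(det[targets], "solved",
                                         "undetermined"), targets))
}

.truncate_code <- function(codes, level) {
  vapply(strsplit(codes, ".", fixed = TRUE), function(v)
    paste(head(v, level), collapse = "."), character(1))
}

#' Condition-dependent abundance ratios by functional category
#'
#' Per complex the abundance ratio is its copy number in minimal (SD) media
#' over rich (YEPD) media; complexes with a YEPD copy number below `1e-9`
#' are excluded (and counted). Categories are function codes truncated to
#' `level` hierarchy fields; a complex with several functions contributes to
#' every matching category. Each complex is also classified by its ratio:
#' above 120%, below 80%, or between (inclusive bounds fall in the middle
#' class).
#'
#' @param sol_sd,sol_yepd [solve_abundance()] results over the same complex
#'   set (SD and YEPD conditions).
#' @param functions a `function_solution` providing complex-function
#'   assignments.
#' @param level hierarchy depth for category truncation (1 = top level).
#' @param confidence use `"raw"` (all) or `"HC"` assignments.
#' @return data.frame (category, mean_ratio, n_complexes, n_up, n_down,
#'   n_mid) with attribute `n_excluded`.
#' @export
abundance_ratio_by_category <- function(sol_sd, sol_yepd, functions,
                                        level = 2,
                                        confidence = c("raw", "HC")) {
  confidence <- match.arg(confidence)
  stopifnot(identical(sort(names(sol_sd$c)), sort(names(sol_yepd$c))))
  asg <- functions$assignments
  if (confidence == "HC") {
    if (is.null(asg$confidence) || all(is.na(asg$confidence)))
      stop("run hc_filter() before requesting HC categories", call. = FALSE)
    asg <- asg[asg$confidence == "HC", , drop = FALSE]
  }
  if (nrow(asg) == 0)
    return(structure(data.frame(category = character(),
                                mean_ratio = numeric(),
                                n_complexes = integer(), n_up = integer(),
                                n_down = integer(), n_mid = integer()),
                     n_excluded = 0L))
  yepd <- sol_yepd$c[asg$complex]
  ok <- yepd > 1e-9
  n_excluded <- length(unique(asg$complex[!ok]))
  asg <- asg[ok, , drop = FALSE]
  ratio <- sol_sd$c[asg$complex] / sol_yepd$c[asg$complex]
  cat_code <- .truncate_code(asg$code, level)
  key <- paste(cat_code, asg$complex, sep = "\r")
  keep <- !duplicated(key)          # one contribution per (category, complex)
  cat_code <- cat_code[keep]; ratio <- ratio[keep]
  cls <- ifelse(ratio > 1.2, "up", ifelse(ratio < 0.8, "down", "mid"))
  out <- do.call(rbind, lapply(split(seq_along(ratio), cat_code), function(ix)
    data.frame(mean_ratio = mean(ratio[ix]), n_complexes = length(ix),
               n_up = sum(cls[ix] == "up"), n_down = sum(cls[ix] == "down"),
               n_mid = sum(cls[ix] == "mid"))))
  out <- data.frame(category = rownames(out), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out[order(out$category), , drop = FALSE],
            n_excluded = n_excluded)
}
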