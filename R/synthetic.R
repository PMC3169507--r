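# run expr under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# wire complex sizes to protein degrees by stub pairing; duplicate
# (complex, protein) pairs are repaired by reshuffling the protein ends of
# offending edges together with as many random clean edges
.pair_stubs <- function(sizes, degrees, max_passes = 2000) {
  cs <- rep(seq_along(sizes), sizes)
  ps <- sample(rep(seq_along(degrees), degrees))
  if (length(cs) != length(ps))
    stop("stub counts differ: ", length(cs), " vs ", length(ps),
         call. = FALSE)
  for (pass in seq_len(max_passes)) {
    key <- paste(cs, ps, sep = "\r")
    dup <- which(duplicated(key))
    if (length(dup) == 0)
      return(data.frame(complex = cs, protein = ps))
    clean <- setdiff(seq_along(cs), dup)
    oth <- sample(clean, min(length(dup), length(clean)))
    idx <- c(dup, oth)
    ps[idx] <- sample(ps[idx])
  }
  stop("could not wire a simple bipartite graph after ", max_passes,
       " repair passes; lower the mean complex size or membership",
       call. = FALSE)
}

#' Generate a synthetic complexome with planted ground truth
#'
#' Emulates the structure of the yeast complexome: complex sizes and protein
#' membership counts are drawn from truncated geometric distributions (the
#' discrete exponential shape observed in TAP-MS complex data), wired by a
#' bipartite configuration model with repair of parallel edges. Each complex
#' labels a fixed fraction of its members core (at least one). Complex copy
#' numbers are planted log-normally per condition; protein abundances are
#' the core-formed demand plus nonnegative exponential surplus, so the
#' planted truth always satisfies the LP availability constraint. Functions
#' are planted on complexes, copied to their core proteins, and then masked
#' at the dropout rate to create unknowns.
#'
#' Defaults mirror the scale of the curated yeast dataset: 491 complexes,
#' 1,491 proteins, mean complex size 13.41, mean protein membership 4.42,
#' 325 function codes, rich/minimal media conditions.
#'
#' @param M,N numbers of complexes and proteins.
#' @param mean_complex_size,mean_membership target means of the truncated
#'   geometric size/degree distributions.
#' @param core_fraction fraction of each complex's members labelled core.
#' @param copy_meanlog,copy_sdlog log-normal parameters of the planted copy
#'   numbers in the first condition (arbitrary units).
#' @param ratio_sdlog log-normal sd of the per-complex copy-number ratio
#'   between conditions.
#' @param noise mean surplus abundance as a fraction of each protein's
#'   formed demand (0 = exact balance).
#' @param n_functions number of dotted hierarchical function codes.
#' @param complexes_per_function planted complexes per function.
#' @param dropout probability that a planted protein annotation is masked.
#' @param conditions condition labels.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return List with `dataset` ([complexome_dataset()]), `abundance`
#'   ([abundance_table()]), `functions` ([function_table()]), and `truth`
#'   (planted `c_star` matrix, protein abundance matrix `p`, full
#'   `annotations`, `planted` complex-function pairs).
#' @export
generate_complexome <- function(M = 491, N = 1491,
                                mean_complex_size = 13.41,
                                mean_membership = 4.42,
                                core_fraction = 0.25,
                                copy_meanlog = log(500), copy_sdlog = 1,
                                ratio_sdlog = 0.5,
                                noise = 0.1,
                                n_functions = 325,
                                complexes_per_function = 1,
                                dropout = 0.2,
                                conditions = c("YEPD", "SD"),
                                seed = 1) {
  stopifnot(M >= 1, N >= 2, core_fraction >= 0, core_fraction <= 1,
            dropout >= 0, dropout <= 1, noise >= 0, n_functions <= M)
  .with_seed(seed, {
    size_max <- min(N, max(20, round(8 * mean_complex_size)))
    deg_max <- min(M, max(10, round(8 * mean_membership)))
    sizes <- sample_pmf(M, geometric_pmf(mean_complex_size, 2, size_max))
    degrees <- sample_pmf(N, geometric_pmf(mean_membership, 1, deg_max))
    # reconcile stub totals: nudge protein degrees first, complex sizes if
    # the degree bounds leave no slack
    diff <- sum(sizes) - sum(degrees)
    while (diff != 0) {
      if (diff > 0) {
        el <- which(degrees < deg_max)
        if (length(el) > 0) {
          up <- sample(el, min(diff, length(el)))
          degrees[up] <- degrees[up] + 1L
        } else {
          el <- which(sizes > 2)
          if (length(el) == 0)
            stop("cannot reconcile stub totals; adjust the mean parameters",
                 call. = FALSE)
          dn <- sample(el, min(diff, length(el)))
          sizes[dn] <- sizes[dn] - 1L
        }
      } else {
        el <- which(degrees > 1)
        if (length(el) > 0) {
          dn <- sample(el, min(-diff, length(el)))
          degrees[dn] <- degrees[dn] - 1L
        } else {
          el <- which(sizes < size_max)
          if (length(el) == 0)
            stop("cannot reconcile stub totals; adjust the mean parameters",
                 call. = FALSE)
          up <- sample(el, min(-diff, length(el)))
          sizes[up] <- sizes[up] + 1L
        }
      }
      diff <- sum(sizes) - sum(degrees)
    }
    cx_ids <- sprintf("cx%04d", seq_len(M))
    pr_ids <- sprintf("p%05d", seq_len(N))
    edges <- .pair_stubs(sizes, degrees)
    memb <- data.frame(complex = cx_ids[edges$complex],
                       protein = pr_ids[edges$protein],
                       role = "attachment", copies = 1L,
                       stringsAsFactors = FALSE)
    for (j in seq_len(M)) {
      rows <- which(edges$complex == j)
      n_core <- max(1L, round(core_fraction * length(rows)))
      memb$role[sample(rows, n_core)] <- "core"
    }
    dataset <- complexome_dataset(memb)

    # planted copy numbers and abundances
    c_star <- matrix(NA_real_, M, length(conditions),
                     dimnames = list(cx_ids, conditions))
    c_star[, 1] <- rlnorm(M, copy_meanlog, copy_sdlog)
    for (ci in seq_along(conditions)[-1])
      c_star[, ci] <- c_star[, 1] * rlnorm(M, 0, ratio_sdlog)
    core <- memb[memb$role == "core", , drop = FALSE]
    Score <- Matrix::sparseMatrix(i = match(core$protein, pr_ids),
                                  j = match(core$complex, cx_ids),
                                  x = core$copies, dims = c(N, M),
                                  dimnames = list(pr_ids, cx_ids))
    demand <- as.matrix(Score %*% c_star)
    ref <- mean(demand[demand > 0])
    p <- demand
    if (noise > 0) {
      scale <- noise * pmax(demand, ref * (demand == 0))
      p <- demand + matrix(rexp(length(demand)), nrow(demand)) * scale
    }
    ab <- abundance_table(data.frame(
      protein = rep(pr_ids, length(conditions)),
      condition = rep(conditions, each = N),
      abundance = as.vector(p)), conditions = conditions)

    # planted functions on complexes, copied to core proteins
    codes <- sprintf("%02d.%02d.%02d",
                     (seq_len(n_functions) - 1) %/% 25 + 1,
                     ((seq_len(n_functions) - 1) %/% 5) %% 5 + 1,
                     (seq_len(n_functions) - 1) %% 5 + 1)
    planted <- data.frame(
      code = rep(codes, complexes_per_function),
      complex = cx_ids[as.vector(replicate(complexes_per_function,
                                           sample(M, n_functions,
                                                  replace = FALSE)))],
      stringsAsFactors = FALSE)
    ann <- merge(planted, core[, c("complex", "protein")], by = "complex")
    ann <- unique(ann[, c("protein", "code")])
    keep <- runif(nrow(ann)) >= dropout
    observed <- ann[keep, , drop = FALSE]
    entries <- split(observed$code, observed$protein)
    functions <- function_table(entries)

    list(dataset = dataset, abundance = ab, functions = functions,
         truth = list(c_star = c_star, p = p, annotations = ann,
                      planted = planted[order(planted$code), ],
                      sizes = sizes, degrees = degrees, seed = seed))
  })
}

#' The three-complex worked example
#'
#' The canonical toy complexome: complex A with proteins a, b, c; complex B
#' with b, d, e; complex C with b and e (all memberships core). Protein b is
#' the shared hub: its bipartite degree is 3, and in the protein projection
#' the link (b, e) has weight 2 because b and e share complexes B and C.
#'
#' @return A [complexome_dataset()] with 3 complexes, 5 proteins, 8
#'   memberships.
#' @export
figure1_toy <- function() {
  complexome_dataset(data.frame(
    complex = c("A", "A", "A", "B", "B", "B", "C", "C"),
    protein = c("a", "b", "c", "b", "d", "e", "b", "e"),
    role = "core", stringsAsFactors = FALSE))
}

#' Simulate a configuration-model bipartite graph from degree pmfs
#'
#' Draws protein membership counts from `p_protein` and complex sizes from
#' `p_complex` (adding complexes until the stub totals match, trimming the
#' last), wires them uniformly at random with repair of parallel edges, and
#' returns the dataset. Proteins drawn with degree 0 stay isolated and are
#' counted, so empirical projected-degree distributions can include them.
#'
#' @param n_proteins number of proteins.
#' @param p_protein,p_complex [pmf()]s of membership counts and sizes.
#' @param seed RNG seed.
#' @return List with `dataset` (all-core [complexome_dataset()]) and
#'   `n_proteins` (including degree-0 proteins absent from the dataset).
#' @export
simulate_bipartite <- function(n_proteins, p_protein, p_complex, seed = 1) {
  .with_seed(seed, {
    degrees <- sample_pmf(n_proteins, p_protein)
    total <- sum(degrees)
    sizes <- integer(0)
    while (sum(sizes) < total)
      sizes <- c(sizes, sample_pmf(max(16, total %/% 4), p_complex))
    cum <- cumsum(sizes)
    mcount <- which(cum >= total)[1]
    sizes <- sizes[seq_len(mcount)]
    sizes[mcount] <- sizes[mcount] - (cum[mcount] - total)
    sizes <- sizes[sizes > 0]
    pr_ids <- sprintf("p%06d", seq_len(n_proteins))
    cx_ids <- sprintf("cx%05d", seq_along(sizes))
    pos <- which(degrees > 0)
    edges <- .pair_stubs(sizes, degrees[pos])
    ds <- complexome_dataset(data.frame(
      complex = cx_ids[edges$complex],
      protein = pr_ids[pos][edges$protein],
      role = "core", stringsAsFactors = FALSE))
    list(dataset = ds, n_proteins = n_proteins)
  })
}

#' Empirical projected-degree pmf of a simulated bipartite graph
#'
#' @param sim a [simulate_bipartite()] result.
#' @return A [pmf()] over projected protein degrees 0..max, counting
#'   proteins isolated in (or absent from) the projection as degree 0.
#' @export
empirical_projected_pmf <- function(sim) {
  proj <- project(build_bipartite(sim$dataset), "protein")
  d <- .proj_degrees(proj)
  all_d <- c(d, integer(sim$n_proteins - length(d)))
  pmf(tabulate(all_d + 1L, nbins = max(all_d) + 1L))
}
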