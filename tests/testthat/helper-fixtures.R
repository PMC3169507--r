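# fixtures and independent oracles shared across the suite

write_tsv_fixture <- function(df, dir = tempdir(), name = NULL) {
  path <- if (is.null(name)) tempfile(tmpdir = dir, fileext = ".tsv") else
    file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

figure1_memberships <- function() {
  data.frame(complex = c("A", "A", "A", "B", "B", "B", "C", "C"),
             protein = c("a", "b", "c", "b", "d", "e", "b", "e"),
             role = "core", stringsAsFactors = FALSE)
}

toy_abundance_df <- function(proteins, values, condition = "YEPD") {
  data.frame(protein = proteins, condition = condition, abundance = values,
             stringsAsFactors = FALSE)
}

# ---- LP oracles -----------------------------------------------------------

# exact: the optimum of max w'x s.t. Ax <= b, x >= 0 sits on a vertex, i.e.
# a basic solution where n of the m + n constraint hyperplanes are active
lp_vertex_oracle <- function(A, b, w) {
  m <- nrow(A); n <- ncol(A)
  G <- rbind(A, -diag(n))          # rows: Ax <= b and -x <= 0
  h <- c(b, numeric(n))
  best <- -Inf; best_x <- NULL
  for (idx in utils::combn(m + n, n, simplify = FALSE)) {
    Gi <- G[idx, , drop = FALSE]
    if (abs(det(Gi)) < 1e-10) next
    x <- tryCatch(solve(Gi, h[idx]), error = function(e) NULL)
    if (is.null(x)) next
    if (all(G %*% x <= h + 1e-8)) {
      v <- sum(w * x)
      if (v > best + 1e-12) { best <- v; best_x <- x }
    }
  }
  list(value = best, x = best_x)
}

# literal fine-grid brute force (step 0.01 on [0, max b]); tractable for
# one or two complexes only
lp_grid_oracle <- function(A, b, w, step = 0.01) {
  n <- ncol(A)
  stopifnot(n <= 2)
  grid <- seq(0, max(b), by = step)
  if (n == 1) {
    X <- matrix(grid, ncol = 1)
  } else {
    X <- as.matrix(expand.grid(grid, grid))
  }
  feas <- rowSums(sweep(X %*% t(A), 2, b) > 1e-9) == 0
  max((X %*% w)[feas])
}

random_lp_instance <- function(seed) {
  set.seed(seed)
  M <- sample(1:4, 1)
  N <- sample(pmax(M, 2):8, 1)
  repeat {
    S <- matrix(rbinom(N * M, 1, 0.45), N, M)
    if (all(colSums(S) > 0) && all(rowSums(S) > 0)) break
  }
  p <- round(runif(N, 0.5, 5), 2)
  list(S = S, p = p,
       complexes = sprintf("J%02d", seq_len(M)),
       proteins = sprintf("x%02d", seq_len(N)))
}

lp_instance_dataset <- function(inst) {
  idx <- which(inst$S > 0, arr.ind = TRUE)
  complexome_dataset(data.frame(complex = inst$complexes[idx[, 2]],
                                protein = inst$proteins[idx[, 1]],
                                role = "core", stringsAsFactors = FALSE))
}

# ---- set cover oracle -----------------------------------------------------

# exhaustive: DP over all subsets by bitmask; returns the optimum size, all
# optimal covers, and the sets present in every optimal cover
cover_enumerate <- function(sets, n_elem) {
  n <- length(sets)
  stopifnot(n <= 15)
  full <- bitwShiftL(1L, n_elem) - 1L
  smask <- vapply(sets, function(s)
    Reduce(bitwOr, bitwShiftL(1L, s - 1L), 0L), integer(1))
  nmask <- bitwShiftL(1L, n)
  cover <- integer(nmask)
  pop <- integer(nmask)
  for (m in seq_len(nmask - 1L)) {
    low <- bitwAnd(m, -m)
    rest <- bitwAnd(m, m - 1L)
    bit <- as.integer(round(log2(low)))
    cover[m + 1L] <- bitwOr(cover[rest + 1L], smask[bit + 1L])
    pop[m + 1L] <- pop[rest + 1L] + 1L
  }
  ok <- which(cover == full) - 1L
  if (length(ok) == 0) return(list(size = Inf, optima = list(),
                                   in_all = integer(0)))
  msize <- min(pop[ok + 1L])
  opt <- ok[pop[ok + 1L] == msize]
  in_all <- which(bitwAnd(Reduce(bitwAnd, opt), bitwShiftL(1L,
                                                           0:(n - 1))) > 0)
  optima <- lapply(opt, function(m) which(bitwAnd(m, bitwShiftL(1L,
                                                                0:(n - 1))) > 0))
  list(size = msize, optima = optima, in_all = in_all)
}

random_cover_instance <- function(seed) {
  set.seed(seed)
  n_sets <- sample(3:15, 1)
  n_elem <- sample(3:12, 1)
  repeat {
    memb <- matrix(rbinom(n_elem * n_sets, 1, 0.3), n_elem, n_sets)
    keep <- colSums(memb) > 0
    memb <- memb[, keep, drop = FALSE]
    if (ncol(memb) >= 2 && all(rowSums(memb) > 0)) break
  }
  list(memb = memb, n_elem = n_elem,
       complexes = sprintf("S%02d", seq_len(ncol(memb))),
       proteins = sprintf("e%02d", seq_len(n_elem)))
}

# run the package's assignment pipeline on a single-function cover instance
cover_instance_solution <- function(inst) {
  idx <- which(inst$memb > 0, arr.ind = TRUE)
  ds <- complexome_dataset(data.frame(complex = inst$complexes[idx[, 2]],
                                      protein = inst$proteins[idx[, 1]],
                                      role = "core",
                                      stringsAsFactors = FALSE))
  fn <- function_table(setNames(as.list(rep("01.01", inst$n_elem)),
                                inst$proteins))
  pb <- build_function_problem(ds, fn)
  hc_filter(pb, solve_function_assignment(pb))
}

# identifiable abundance fixture: every complex carries dedicated core
# proteins, so any training subset retaining one of them pins its column
identifiable_fixture <- function(M = 12, dedicated = 4, shared = 6,
                                 seed = 99) {
  set.seed(seed)
  cx <- sprintf("cx%02d", seq_len(M))
  memb <- do.call(rbind, lapply(seq_len(M), function(j)
    data.frame(complex = cx[j],
               protein = sprintf("d%02d_%d", j, seq_len(dedicated)),
               role = "core", stringsAsFactors = FALSE)))
  for (s in seq_len(shared)) {
    in_cx <- sample(M, 2)
    memb <- rbind(memb, data.frame(complex = cx[in_cx],
                                   protein = sprintf("s%02d", s),
                                   role = "core", stringsAsFactors = FALSE))
  }
  ds <- complexome_dataset(memb)
  c_star <- setNames(round(runif(M, 1, 20), 3), cx)
  core <- ds$memberships
  demand <- tapply(c_star[core$complex], core$protein, sum)
  ab <- abundance_table(toy_abundance_df(names(demand),
                                         as.numeric(demand)))
  list(dataset = ds, abundance = ab, c_star = c_star)
}
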