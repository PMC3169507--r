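# Dense tableau simplex for LPs of the form
#   maximize  obj'x   subject to  A x <= b,  x >= 0,  with b >= 0.
# The all-slack basis is feasible (b >= 0), so no phase 1 is needed. Entering
# variable: most negative reduced cost (lowest index on ties); leaving: min
# ratio, lowest row on ties. After a long degenerate stretch the pivot rule
# switches to Bland's, which cannot cycle. Deterministic for a fixed column
# order.

lp_max <- function(A, b, obj, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(obj) == n)
  if (any(b < -tol)) stop("lp_max requires b >= 0", call. = FALSE)
  b <- pmax(b, 0)
  if (m == 0)
    stop("lp_max: no constraints; problem unbounded unless obj <= 0",
         call. = FALSE)
  Tb <- cbind(A, diag(m), b)
  Tb <- rbind(Tb, c(-obj, numeric(m), 0))
  basis <- n + seq_len(m)
  last <- n + m + 1L
  bland_after <- 20L * (m + n)
  maxit <- 200L * (m + n) + 10000L
  for (it in seq_len(maxit)) {
    cost <- Tb[m + 1L, seq_len(n + m)]
    neg <- which(cost < -tol)
    if (length(neg) == 0) break
    je <- if (it <= bland_after) neg[which.min(cost[neg])] else neg[1L]
    col <- Tb[seq_len(m), je]
    pos <- which(col > tol)
    if (length(pos) == 0)
      stop("lp_max: unbounded objective", call. = FALSE)
    ratios <- Tb[pos, last] / col[pos]
    best <- min(ratios)
    cand <- pos[ratios <= best + tol]
    jr <- if (length(cand) == 1L) cand else cand[which.min(basis[cand])]
    piv <- Tb[jr, je]
    Tb[jr, ] <- Tb[jr, ] / piv
    other <- setdiff(seq_len(m + 1L), jr)
    fac <- Tb[other, je]
    nz <- which(abs(fac) > 0)
    if (length(nz) > 0)
      Tb[other[nz], ] <- Tb[other[nz], ] - outer(fac[nz], Tb[jr, ])
    basis[jr] <- je
    if (it == maxit)
      stop("lp_max: iteration limit reached", call. = FALSE)
  }
  x <- numeric(n)
  inb <- which(basis <= n)
  x[basis[inb]] <- Tb[inb, last]
  x[x < 0 & x > -tol] <- 0
  list(x = x, value = Tb[m + 1L, last], iterations = NA_integer_)
}
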