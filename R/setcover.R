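# Exact minimum set cover by depth-first branch and bound, deterministic for
# a fixed set order. Two objectives:
#   mode "complexes": minimize the number of chosen sets;
#   mode "proteins":  minimize |union of new_elems over chosen sets| (the
#                     newly covered core proteins), ties broken by fewer sets.
# Branching is on the uncovered element covered by the fewest sets; candidate
# sets are tried in increasing index order. Used per function code, where the
# global assignment problem decomposes into independent cover instances.

set_cover_solve <- function(sets, n_elem, mode = c("complexes", "proteins"),
                            new_elems = NULL, forbid = integer(0)) {
  mode <- match.arg(mode)
  avail <- setdiff(seq_along(sets), forbid)
  if (n_elem == 0)
    return(list(feasible = TRUE, size = 0L, n_new = 0L, cover = integer(0)))
  if (!all(seq_len(n_elem) %in% unlist(sets[avail])))
    return(list(feasible = FALSE, size = Inf, n_new = Inf,
                cover = integer(0)))
  covers_of <- lapply(seq_len(n_elem), function(e)
    avail[vapply(sets[avail], function(s) e %in% s, logical(1))])
  if (mode == "proteins" && is.null(new_elems))
    stop("new_elems required for the min-proteins objective", call. = FALSE)
  max_size <- max(lengths(sets[avail]))

  # greedy upper bound (max new coverage, lowest index on ties)
  uncovered <- rep(TRUE, n_elem)
  greedy <- integer(0)
  while (any(uncovered)) {
    gains <- vapply(avail, function(s) sum(uncovered[sets[[s]]]), integer(1))
    pick <- avail[which.max(gains)]
    greedy <- c(greedy, pick)
    uncovered[sets[[pick]]] <- FALSE
  }
  best_cover <- sort(greedy)
  best_size <- length(greedy)
  best_new <- if (mode == "proteins")
    length(unique(unlist(new_elems[greedy]))) else NA_integer_

  better <- function(np, ns) {
    if (mode == "complexes") return(ns < best_size)
    np < best_new || (np == best_new && ns < best_size)
  }
  # lower-bound prune: can the current partial still beat the incumbent?
  hopeless <- function(np, ns, n_unc) {
    need <- if (n_unc > 0) ceiling(n_unc / max_size) else 0L
    if (mode == "complexes") return(ns + need >= best_size)
    if (np > best_new) return(TRUE)
    np == best_new && ns + need >= best_size
  }

  new_mask <- if (mode == "proteins")
    rep(FALSE, max(c(0, unlist(new_elems), 0))) else logical(0)

  recurse <- function(uncovered, chosen, new_mask) {
    n_unc <- sum(uncovered)
    np <- if (mode == "proteins") sum(new_mask) else NA_integer_
    if (n_unc == 0) {
      if (better(np, length(chosen))) {
        best_size <<- length(chosen)
        best_cover <<- sort(chosen)
        if (mode == "proteins") best_new <<- np
      }
      return(invisible())
    }
    if (hopeless(np, length(chosen), n_unc)) return(invisible())
    elems <- which(uncovered)
    ncov <- lengths(covers_of)[elems]
    e <- elems[which.min(ncov)]
    for (s in covers_of[[e]]) {
      if (s %in% chosen) next
      unc2 <- uncovered
      unc2[sets[[s]]] <- FALSE
      nm2 <- new_mask
      if (mode == "proteins" && length(new_elems[[s]]) > 0)
        nm2[new_elems[[s]]] <- TRUE
      recurse(unc2, c(chosen, s), nm2)
    }
    invisible()
  }
  recurse(rep(TRUE, n_elem), integer(0), new_mask)
  list(feasible = TRUE, size = best_size,
       n_new = if (mode == "proteins") best_new else NA_integer_,
       cover = best_cover)
}

# TRUE iff set j belongs to every optimal cover: forbid j and test whether
# the optimum strictly worsens (or the instance becomes infeasible).
set_cover_in_all_optima <- function(sets, n_elem, j, opt,
                                    mode = c("complexes", "proteins"),
                                    new_elems = NULL) {
  mode <- match.arg(mode)
  alt <- set_cover_solve(sets, n_elem, mode, new_elems, forbid = j)
  if (!alt$feasible) return(TRUE)
  if (mode == "complexes") return(alt$size > opt$size)
  alt$n_new > opt$n_new || (alt$n_new == opt$n_new && alt$size > opt$size)
}
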