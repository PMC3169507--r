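#' Build a function assignment problem
#'
#' Function assignment uses both core and attachment memberships: allowing
#' every alternative way of covering an annotation makes the functions that
#' survive minimization more certain. Annotated proteins absent from every
#' complex cannot constrain any assignment and are excluded (and reported).
#'
#' @param dataset a [complexome_dataset()].
#' @param functions a [function_table()].
#' @return Object of class `function_problem`: list with the binary
#'   membership matrix `U` (all roles), the core-only matrix `U_core`, the
#'   per-code protein lists `code_proteins`, the code universe `codes`, and
#'   the excluded `orphans`.
#' @export
build_function_problem <- function(dataset, functions) {
  U <- incidence_matrix(dataset, "all")
  U_core <- incidence_matrix(dataset, "core")
  annotated <- names(functions$entries)
  orphans <- setdiff(annotated, dataset$proteins)
  if (length(orphans) > 0)
    message(length(orphans),
            " annotated protein(s) are in no complex and impose no",
            " constraint")
  usable <- intersect(annotated, dataset$proteins)
  pairs <- data.frame(
    protein = rep(usable, lengths(functions$entries[usable])),
    code = unlist(functions$entries[usable], use.names = FALSE),
    stringsAsFactors = FALSE)
  code_proteins <- split(pairs$protein, pairs$code)
  structure(list(U = U, U_core = U_core, codes = sort(unique(pairs$code)),
                 code_proteins = code_proteins, orphans = orphans,
                 complexes = colnames(U)),
            class = "function_problem")
}

# per-code cover instance: elements are the annotated proteins, candidate
# sets the complexes containing at least one of them
.cover_instance <- function(problem, code) {
  prot <- problem$code_proteins[[code]]
  Usub <- problem$U[prot, , drop = FALSE]
  cand <- which(Matrix::colSums(Usub) > 0)
  sets <- lapply(cand, function(j) which(Usub[, j] > 0))
  list(proteins = prot, cand = colnames(problem$U)[cand], sets = sets,
       n_elem = length(prot))
}

# indices (within `prot`) of core proteins NOT annotated with the code, per
# candidate complex: the "newly assigned" proteins of the min-proteins
# objective
.new_core_elems <- function(problem, code, cand) {
  ann <- problem$code_proteins[[code]]
  lapply(cand, function(j) {
    members <- rownames(problem$U_core)[problem$U_core[, j] > 0]
    new <- setdiff(members, ann)
    match(new, rownames(problem$U))       # stable global indexing
  })
}

#' Assign functions to complexes by per-function minimum set cover
#'
#' Every function carried by an annotated protein must be carried by at
#' least one complex containing that protein (the covering constraint). The
#' problem decomposes into one minimum set cover instance per function code;
#' each is solved exactly. The default objective (`min_complexes`) minimizes
#' the number of complexes assigned with each function; the alternative
#' (`min_proteins`) minimizes the number of core proteins newly reached by
#' the assignment, breaking ties by fewer complexes.
#'
#' @param problem a [build_function_problem()] result.
#' @param variant `"min_complexes"` or `"min_proteins"`.
#' @return Object of class `function_solution`: list with `assignments`
#'   (data.frame complex / code / confidence / sources), per-code optima
#'   `m_star`, and the `variant`.
#' @export
solve_function_assignment <- function(problem,
                                      variant = c("min_complexes",
                                                  "min_proteins")) {
  variant <- match.arg(variant)
  mode <- if (variant == "min_complexes") "complexes" else "proteins"
  rows <- list(); m_star <- setNames(integer(length(problem$codes)),
                                     problem$codes)
  for (code in problem$codes) {
    inst <- .cover_instance(problem, code)
    if (inst$n_elem == 0 || length(inst$cand) == 0) {
      m_star[code] <- 0L
      next
    }
    nel <- if (mode == "proteins")
      .new_core_elems(problem, code,
                      match(inst$cand, colnames(problem$U))) else NULL
    opt <- set_cover_solve(inst$sets, inst$n_elem, mode, nel)
    m_star[code] <- as.integer(opt$size)
    if (length(opt$cover) > 0) {
      cx <- inst$cand[opt$cover]
      sources <- vapply(opt$cover, function(s)
        paste(sort(inst$proteins[inst$sets[[s]]]), collapse = ";"),
        character(1))
      rows[[code]] <- data.frame(complex = cx, code = code,
                                 confidence = NA_character_,
                                 sources = sources,
                                 stringsAsFactors = FALSE)
    }
  }
  asg <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(complex = character(), code = character(),
               confidence = character(), sources = character(),
               stringsAsFactors = FALSE)
  asg <- asg[order(asg$complex, asg$code), , drop = FALSE]
  rownames(asg) <- NULL
  structure(list(assignments = asg, m_star = m_star, variant = variant,
                 codes = problem$codes),
            class = "function_solution")
}

#' @export
print.function_solution <- function(x, ...) {
  nhc <- sum(x$assignments$confidence == "HC", na.rm = TRUE)
  cat("function solution (", x$variant, "): ", nrow(x$assignments),
      " assignments over ", length(x$codes), " codes",
      if (!all(is.na(x$assignments$confidence)))
        paste0(", ", nhc, " HC") else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.function_solution <- function(x, ...) {
  cbind(x$assignments, variant = rep(x$variant,
                                     nrow(x$assignments)))
}

#' Label high-confidence (all-optima) assignments
#'
#' The cover optimum is rarely unique. An assignment (complex j, function k)
#' is high-confidence (HC) when j belongs to *every* optimal cover of
#' instance k, decided exactly by re-solving the instance with j forbidden
#' and testing whether the optimum strictly worsens. All other reported
#' assignments keep the `"raw"` label.
#'
#' @param problem the [build_function_problem()] the solution came from.
#' @param solution a [solve_function_assignment()] result.
#' @return The solution with its `confidence` column filled
#'   (`"HC"`/`"raw"`).
#' @export
hc_filter <- function(problem, solution) {
  asg <- solution$assignments
  mode <- if (solution$variant == "min_complexes") "complexes" else
    "proteins"
  for (code in unique(asg$code)) {
    inst <- .cover_instance(problem, code)
    nel <- if (mode == "proteins")
      .new_core_elems(problem, code,
                      match(inst$cand, colnames(problem$U))) else NULL
    opt <- set_cover_solve(inst$sets, inst$n_elem, mode, nel)
    sel <- which(asg$code == code)
    for (r in sel) {
      j <- match(asg$complex[r], inst$cand)
      asg$confidence[r] <- if (set_cover_in_all_optima(
        inst$sets, inst$n_elem, j, opt, mode, nel)) "HC" else "raw"
    }
  }
  solution$assignments <- asg
  solution
}

#' Re-substitute assigned complex functions to proteins
#'
#' A protein is conjectured to perform function k if it lacks the annotation
#' but is a *core* member of a complex assigned with k (a protein's main
#' biological functions are exercised through its core memberships). Each
#' prediction lists its source complexes.
#'
#' @param solution a [solve_function_assignment()] result (after
#'   [hc_filter()] if `hc_only`).
#' @param dataset the [complexome_dataset()].
#' @param functions the [function_table()] of known annotations.
#' @param hc_only restrict to HC assignments.
#' @return data.frame (protein, code, sources) of new predictions.
#' @export
resubstitute_protein_functions <- function(solution, dataset, functions,
                                           hc_only = TRUE) {
  asg <- solution$assignments
  if (hc_only) {
    if (all(is.na(asg$confidence)) && nrow(asg) > 0)
      stop("run hc_filter() before hc_only re-substitution", call. = FALSE)
    asg <- asg[asg$confidence == "HC", , drop = FALSE]
  }
  empty <- data.frame(protein = character(), code = character(),
                      sources = character(), stringsAsFactors = FALSE)
  if (nrow(asg) == 0) return(empty)
  core <- dataset$memberships[dataset$memberships$role == "core", ,
                              drop = FALSE]
  hit <- merge(asg[, c("complex", "code")],
               core[, c("complex", "protein")], by = "complex")
  if (nrow(hit) == 0) return(empty)
  known <- functions$entries
  has <- mapply(function(p, k) k %in% known[[p]], hit$protein, hit$code)
  hit <- hit[!has, , drop = FALSE]
  if (nrow(hit) == 0) return(empty)
  key <- paste(hit$protein, hit$code, sep = "\r")
  src <- tapply(hit$complex, key, function(v)
    paste(sort(unique(v)), collapse = ";"))
  parts <- strsplit(names(src), "\r", fixed = TRUE)
  out <- data.frame(protein = vapply(parts, `[`, character(1), 1),
                    code = vapply(parts, `[`, character(1), 2),
                    sources = as.character(src), stringsAsFactors = FALSE)
  out <- out[order(out$protein, out$code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trace the donor proteins of a complex-function assignment
#'
#' Every assignment is forced by the covering constraint, so at least one
#' component protein of the complex must already carry the function: these
#' annotation donors are returned, with their membership roles. This is the
#' provenance chain behind every new protein prediction (the complex an
#' assignment sits on, and the already-annotated component it originates
#' from).
#'
#' @inheritParams resubstitute_protein_functions
#' @param complex,code the assignment to trace.
#' @return data.frame (protein, roles) of donors.
#' @export
trace_function_source <- function(solution, dataset, functions, complex,
                                  code) {
  asg <- solution$assignments
  if (!any(asg$complex == complex & asg$code == code))
    stop("function ", code, " is not assigned to complex ", complex,
         call. = FALSE)
  memb <- dataset$memberships[dataset$memberships$complex == complex, ,
                              drop = FALSE]
  donors <- unique(memb$protein[vapply(memb$protein, function(p)
    code %in% functions$entries[[p]], logical(1))])
  if (length(donors) == 0)
    stop("covering invariant violated: assignment (", complex, ", ", code,
         ") has no annotated donor", call. = FALSE)
  roles <- vapply(donors, function(p)
    paste(sort(unique(memb$role[memb$protein == p])), collapse = ";"),
    character(1))
  data.frame(protein = sort(donors), roles = roles[sort(donors)],
             stringsAsFactors = FALSE)
}
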