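#' Column-mapping dialect for tabular inputs
#'
#' Complexome inputs are headered TSV exports whose column names vary between
#' sources. A dialect maps the canonical column roles used by the readers to
#' the actual header names in a file.
#'
#' @param complex,protein,role,copies headers of the membership table columns.
#'   `role` and `copies` are optional in the file: absent role defaults to
#'   `"core"`, absent copies to 1 (so the stoichiometric count equals the
#'   binary membership indicator).
#' @param condition,abundance headers of the abundance table columns.
#' @param codes header of the function-code column.
#' @param code_sep regular expression splitting multi-code cells.
#' @return A named list of class `complexome_dialect`.
#' @export
#' @examples
#' complexome_dialect(complex = "Complex", protein = "ORF")
complexome_dialect <- function(complex = "complex", protein = "protein",
                               role = "role", copies = "copies",
                               condition = "condition", abundance = "abundance",
                               codes = "funcat", code_sep = "[;|]") {
  structure(list(complex = complex, protein = protein, role = role,
                 copies = copies, condition = condition,
                 abundance = abundance, codes = codes, code_sep = code_sep),
            class = "complexome_dialect")
}

.strip <- function(x) trimws(as.character(x))

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, colClasses = "character", na.strings = NULL)
}

.require_cols <- function(df, cols, path) {
  missing <- setdiff(unlist(cols), names(df))
  if (length(missing) > 0)
    stop("missing required column(s) ", paste(missing, collapse = ", "),
         " in ", path, " (check the dialect mapping)", call. = FALSE)
}

#' Construct a complexome dataset
#'
#' A complexome dataset holds the role-labelled membership list of proteins in
#' complexes. Complex and protein identifiers are opaque case-sensitive
#' strings (whitespace-stripped); each membership carries a role
#' (`"core"` or `"attachment"`) and a stoichiometric count `copies >= 1`.
#' Duplicate (complex, protein, role) rows are collapsed with a warning.
#'
#' @param memberships data.frame with columns `complex`, `protein`, and
#'   optionally `role` and `copies`.
#' @return Object of class `complexome_dataset`: a list with the validated
#'   `memberships` data.frame (lexicographically ordered) and the
#'   deduplicated, sorted `complexes` and `proteins` id vectors.
#' @export
#' @examples
#' complexome_dataset(data.frame(complex = "A", protein = c("a", "b"),
#'                               role = "core"))
complexome_dataset <- function(memberships) {
  m <- as.data.frame(memberships, stringsAsFactors = FALSE)
  if (nrow(m) == 0) {
    m <- data.frame(complex = character(), protein = character(),
                    role = character(), copies = integer(),
                    stringsAsFactors = FALSE)
  }
  if (!all(c("complex", "protein") %in% names(m)))
    stop("memberships must have 'complex' and 'protein' columns", call. = FALSE)
  if (is.null(m$role)) m$role <- rep("core", nrow(m))
  if (is.null(m$copies)) m$copies <- rep(1L, nrow(m))
  m$complex <- .strip(m$complex)
  m$protein <- .strip(m$protein)
  m$role <- .strip(m$role)
  bad <- which(!m$role %in% c("core", "attachment"))
  if (length(bad) > 0)
    stop("malformed role value '", m$role[bad[1]], "' at row ", bad[1],
         " (expected 'core' or 'attachment')", call. = FALSE)
  copies <- suppressWarnings(as.numeric(m$copies))
  if (anyNA(copies) || any(copies < 1) || any(copies != round(copies)))
    stop("copies must be positive integers", call. = FALSE)
  m$copies <- as.integer(copies)
  key <- paste(m$complex, m$protein, m$role, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate membership row(s) collapsed",
            call. = FALSE)
    m <- m[!duplicated(key), , drop = FALSE]
  }
  m <- m[order(m$complex, m$protein, m$role), , drop = FALSE]
  rownames(m) <- NULL
  structure(list(memberships = m[, c("complex", "protein", "role", "copies")],
                 complexes = sort(unique(m$complex)),
                 proteins = sort(unique(m$protein))),
            class = "complexome_dataset")
}

#' @export
print.complexome_dataset <- function(x, ...) {
  cat("complexome dataset:", length(x$complexes), "complexes,",
      length(x$proteins), "proteins,", nrow(x$memberships), "memberships\n")
  tab <- table(factor(x$memberships$role, levels = c("core", "attachment")))
  cat("  roles: core", tab[["core"]], "/ attachment", tab[["attachment"]], "\n")
  invisible(x)
}

#' Read a complex membership table
#'
#' Reads a headered TSV of (complex, protein, role, copies) rows into a
#' validated [complexome_dataset()]. Lines with malformed role values raise a
#' parse error naming the line; duplicate rows are collapsed with a warning.
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect a [complexome_dialect()] mapping column names.
#' @return A [complexome_dataset()].
#' @export
read_complexes <- function(path, dialect = complexome_dialect()) {
  df <- .read_tsv(path)
  .require_cols(df, dialect[c("complex", "protein")], path)
  out <- data.frame(complex = df[[dialect$complex]],
                    protein = df[[dialect$protein]],
                    stringsAsFactors = FALSE)
  out$role <- if (dialect$role %in% names(df)) df[[dialect$role]] else
    rep("core", nrow(out))
  out$copies <- if (dialect$copies %in% names(df)) df[[dialect$copies]] else
    rep(1L, nrow(out))
  ds <- tryCatch(complexome_dataset(out), error = function(e)
    stop(conditionMessage(e), " [while parsing ", path, "]", call. = FALSE))
  message("read ", length(ds$complexes), " complexes / ",
          length(ds$proteins), " proteins (",
          nrow(ds$memberships), " memberships) from ", path)
  ds
}

#' Construct a protein abundance table
#'
#' @param entries data.frame with columns `protein`, `condition`, `abundance`
#'   (nonnegative, arbitrary units; `NA` means unknown).
#' @param conditions declared condition labels; defaults to those observed.
#' @return Object of class `abundance_table`.
#' @export
abundance_table <- function(entries, conditions = NULL) {
  e <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (nrow(e) == 0)
    e <- data.frame(protein = character(), condition = character(),
                    abundance = numeric(), stringsAsFactors = FALSE)
  stopifnot(all(c("protein", "condition", "abundance") %in% names(e)))
  e$protein <- .strip(e$protein)
  e$condition <- .strip(e$condition)
  e$abundance <- as.numeric(e$abundance)
  if (any(e$abundance < 0, na.rm = TRUE))
    stop("abundances must be nonnegative", call. = FALSE)
  if (is.null(conditions)) conditions <- sort(unique(e$condition))
  if (!all(e$condition %in% conditions))
    stop("condition label outside the declared set", call. = FALSE)
  key <- paste(e$protein, e$condition, sep = "\r")
  e <- e[!duplicated(key), , drop = FALSE]
  e <- e[order(e$protein, e$condition), , drop = FALSE]
  rownames(e) <- NULL
  structure(list(entries = e, conditions = conditions),
            class = "abundance_table")
}

#' Read a protein abundance table
#'
#' Blank abundance cells are kept as unknown (`NA`); negative or non-numeric
#' values raise a parse error naming the line.
#'
#' @inheritParams read_complexes
#' @return An [abundance_table()].
#' @export
read_abundance <- function(path, dialect = complexome_dialect()) {
  df <- .read_tsv(path)
  .require_cols(df, dialect[c("protein", "condition", "abundance")], path)
  raw <- .strip(df[[dialect$abundance]])
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & raw != "" & is.na(val))
  if (length(bad) > 0)
    stop("non-numeric abundance '", raw[bad[1]], "' at line ", bad[1] + 1L,
         " of ", path, call. = FALSE)
  neg <- which(!is.na(val) & val < 0)
  if (length(neg) > 0)
    stop("negative abundance at line ", neg[1] + 1L, " of ", path,
         call. = FALSE)
  abundance_table(data.frame(protein = df[[dialect$protein]],
                             condition = df[[dialect$condition]],
                             abundance = val, stringsAsFactors = FALSE))
}

#' Lookup abundances for one condition
#'
#' @param abundance an [abundance_table()].
#' @param condition condition label.
#' @return Named numeric vector of known (non-`NA`) abundances.
#' @export
condition_abundance <- function(abundance, condition) {
  stopifnot(inherits(abundance, "abundance_table"))
  if (!condition %in% abundance$conditions)
    stop("condition '", condition, "' not present (have: ",
         paste(abundance$conditions, collapse = ", "), ")", call. = FALSE)
  e <- abundance$entries
  e <- e[e$condition == condition & !is.na(e$abundance), , drop = FALSE]
  setNames(e$abundance, e$protein)
}

.code_pattern <- "^[0-9]+(\\.[0-9]+)*$"

#' Construct a protein function table
#'
#' Function codes are hierarchical dotted strings (e.g. `"10.03.03"` in the
#' FunCat style); each protein carries a duplicate-free set of codes.
#'
#' @param entries named list mapping protein id to a character vector of codes.
#' @return Object of class `function_table` with fields `entries` (sorted,
#'   deduplicated) and `codes` (the code universe, size `F`).
#' @export
function_table <- function(entries) {
  entries <- as.list(entries)
  if (length(entries) == 0)
    return(structure(list(entries = setNames(list(), character(0)),
                          codes = character(0)), class = "function_table"))
  entries <- entries[order(names(entries))]
  entries <- lapply(entries, function(v) sort(unique(.strip(v))))
  allc <- unlist(entries, use.names = FALSE)
  bad <- allc[!grepl(.code_pattern, allc)]
  if (length(bad) > 0)
    stop("malformed function code '", bad[1], "'", call. = FALSE)
  structure(list(entries = entries, codes = sort(unique(allc))),
            class = "function_table")
}

#' Read a protein function table
#'
#' Multi-code cells are split on the dialect's `code_sep` (default `;` or
#' `|`). In strict mode a code failing the dotted-numeric pattern is a parse
#' error; in lenient mode it is skipped with a warning.
#'
#' @inheritParams read_complexes
#' @param strict logical; error (`TRUE`) or skip with warning (`FALSE`) on
#'   malformed codes.
#' @return A [function_table()].
#' @export
read_functions <- function(path, dialect = complexome_dialect(),
                           strict = TRUE) {
  df <- .read_tsv(path)
  .require_cols(df, dialect[c("protein", "codes")], path)
  proteins <- .strip(df[[dialect$protein]])
  codes <- strsplit(.strip(df[[dialect$codes]]), dialect$code_sep)
  codes <- lapply(codes, function(v) .strip(v[v != ""]))
  for (i in seq_along(codes)) {
    bad <- codes[[i]][!grepl(.code_pattern, codes[[i]])]
    if (length(bad) > 0) {
      if (strict)
        stop("malformed function code '", bad[1], "' at line ", i + 1L,
             " of ", path, call. = FALSE)
      warning("skipping malformed code '", bad[1], "' at line ", i + 1L,
              call. = FALSE)
      codes[[i]] <- setdiff(codes[[i]], bad)
    }
  }
  entries <- split(unlist(codes, use.names = FALSE),
                   rep(proteins, lengths(codes)))
  function_table(entries)
}

#' Write or read solution tables
#'
#' Serializes an abundance or function solution to TSV or JSON such that
#' reading the file back reproduces the assignment content exactly.
#'
#' @param solution an `abundance_solution` or `function_solution`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `write_solutions` returns `path` invisibly; `read_solutions`
#'   returns a data.frame of the assignment rows.
#' @export
write_solutions <- function(solution, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(solution)
  if (format == "tsv") {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' @rdname write_solutions
#' @export
read_solutions <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    df <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                        stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0 && "complex" %in% names(df)) df
  df
}
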