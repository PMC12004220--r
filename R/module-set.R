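#' Construct a module set
#'
#' An ordered collection of disjoint gene modules, the output unit of the
#' clustering step. Module ids are assigned as `M01`, `M02`, ... in order of
#' decreasing module size; ties are broken by the lexicographically smallest
#' member gene. A provenance list snapshots the parameters that produced and
#' filtered the set.
#'
#' @param modules list of non-empty character vectors (gene ids), pairwise
#'   disjoint. Names, if any, are discarded and reassigned.
#' @param provenance named list of parameter snapshots.
#' @return an object of class `ModuleSet`.
#' @export
module_set <- function(modules, provenance = list()) {
  modules <- lapply(modules, as.character)
  if (any(vapply(modules, length, 0L) == 0L)) {
    stop("modules must be non-empty")
  }
  all_genes <- unlist(modules, use.names = FALSE)
  if (anyDuplicated(all_genes)) {
    stop("modules must be pairwise disjoint; duplicated gene(s): ",
         paste(unique(all_genes[duplicated(all_genes)]), collapse = ", "))
  }
  modules <- lapply(modules, function(g) sort(g))
  if (length(modules)) {
    sizes <- vapply(modules, length, 0L)
    firsts <- vapply(modules, function(g) g[[1L]], "")
    ord <- order(-sizes, firsts)
    modules <- modules[ord]
    names(modules) <- sprintf("M%02d", seq_along(modules))
  } else {
    modules <- stats::setNames(list(), character(0))
  }
  structure(list(modules = modules, provenance = provenance),
            class = "ModuleSet")
}

#' @export
print.ModuleSet <- function(x, ...) {
  sizes <- vapply(x$modules, length, 0L)
  cat(sprintf("ModuleSet: %d modules, %d genes\n",
              length(x$modules), sum(sizes)))
  if (length(sizes)) {
    shown <- utils::head(sizes, 10L)
    cat("  sizes:", paste(sprintf("%s=%d", names(shown), shown),
                          collapse = " "),
        if (length(sizes) > 10L) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
length.ModuleSet <- function(x) length(x$modules)

#' Genes of a module set
#' @param ms a `ModuleSet`.
#' @return character vector of all member genes, in module order.
#' @export
module_genes <- function(ms) {
  stopifnot(inherits(ms, "ModuleSet"))
  unlist(ms$modules, use.names = FALSE)
}

#' Write modules in GMT format
#'
#' One tab-separated line per module: id, description, member genes.
#' Module order is preserved.
#'
#' @param ms a `ModuleSet` (may be empty).
#' @param file_path output path.
#' @param description description field written for every module.
#' @export
write_modules_gmt <- function(ms, file_path, description = "coexmod") {
  stopifnot(inherits(ms, "ModuleSet"))
  lines <- vapply(seq_along(ms$modules), function(i) {
    paste(c(names(ms$modules)[i], description, ms$modules[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, file_path)
  invisible(file_path)
}

#' Read modules from GMT
#'
#' @param file_path path to a GMT file.
#' @return a named list module id -> character vector of genes (file order).
#' @export
read_modules_gmt <- function(file_path) {
  if (!file.exists(file_path)) stop("no such file: ", file_path)
  lines <- readLines(file_path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) stop("malformed GMT line: ", ln)
    out[[fields[1L]]] <- fields[-(1:2)]
  }
  out
}

#' Write modules as a two-column TSV (gene, module_id)
#'
#' @param ms a `ModuleSet`.
#' @param file_path output path.
#' @export
write_modules_tsv <- function(ms, file_path) {
  stopifnot(inherits(ms, "ModuleSet"))
  df <- as.data.frame(ms)
  utils::write.table(df, file_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file_path)
}

#' @export
as.data.frame.ModuleSet <- function(x, ...) {
  data.frame(
    gene = unlist(x$modules, use.names = FALSE),
    module_id = rep(names(x$modules), vapply(x$modules, length, 0L)),
    stringsAsFactors = FALSE
  )
}
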