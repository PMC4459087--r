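# File formats: Newick trees (branch lengths in MY for chronograms or in
# substitutions/site for phylograms), TSV calibration tables, TSV age/bias
# tables, JSON run grids, FASTA alignments.

#' Read and write Newick trees
#'
#' Thin wrappers over `ape` that tag the branch-length unit (`"MY"` or
#' `"subst"`) as an attribute and give a positional error on malformed input.
#' Round-trip (`read` then `write` then `read`) preserves topology, labels and
#' branch lengths to better than 1e-9.
#'
#' @param path File path.
#' @param unit Branch-length unit to record: `"MY"` (chronogram) or `"subst"`
#'   (substitutions/site).
#' @return `read_newick()`: an `ape::phylo`. `write_newick()`: `path`,
#'   invisibly.
#' @export
read_newick <- function(path, unit = c("MY", "subst")) {
  unit <- match.arg(unit)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  tree <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    # locate the first structural problem for the error message
    open <- cumsum(
      (strsplit(txt, "")[[1]] == "(") - (strsplit(txt, "")[[1]] == ")")
    )
    pos <- if (any(open < 0)) which(open < 0)[1] else nchar(txt)
    stop("malformed Newick in '", path, "' near character ", pos, call. = FALSE)
  }
  attr(tree, "unit") <- unit
  tree
}

#' @rdname read_newick
#' @param tree An `ape::phylo`.
#' @export
write_newick <- function(tree, path, unit = c("MY", "subst")) {
  unit <- attr(tree, "unit") %||% match.arg(unit)
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Write a dated tree as Newick with node-age labels
#'
#' Node ages (MY) are stored as node labels of the form `age=<MY>`, and branch
#' lengths are in MY.
#'
#' @param dated A `dated_tree` from [date_tree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dated_newick <- function(dated, path) {
  stopifnot(inherits(dated, "dated_tree"))
  tree <- dated$tree
  ntip <- ape::Ntip(tree)
  ages <- dated$estimates$point_age[
    match((ntip + 1):(ntip + tree$Nnode), dated$estimates$node)
  ]
  tree$node.label <- sprintf("age=%.6g", ages)
  # rescale edges so the written tree is the dated chronogram
  node_age <- c(rep(0, ntip), ages)
  tree$edge.length <- node_age[tree$edge[, 1]] - node_age[tree$edge[, 2]]
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read and write calibration tables
#'
#' TSV with columns `clade`, `clade_taxa` (semicolon-joined tip labels),
#' `min_age` (MY), `shape` (`lognormal`/`normal`/`uniform`) and `spread`.
#' An empty file yields an empty table. Validation: positive `min_age`, known
#' `shape`, and (when a tree is given) monophyly of every clade.
#'
#' @param path TSV path.
#' @param tree Optional `ape::phylo` against which clades are validated.
#' @return A calibration tibble.
#' @export
read_calibrations <- function(path, tree = NULL) {
  empty <- tibble::tibble(
    clade = character(), clade_taxa = character(), min_age = numeric(),
    shape = character(), spread = numeric()
  )
  if (length(readLines(path, warn = FALSE)) == 0) return(empty)
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      clade = readr::col_character(),
      clade_taxa = readr::col_character(),
      min_age = readr::col_double(),
      shape = readr::col_character(),
      spread = readr::col_double()
    )
  )
  if (nrow(tab) == 0) return(empty)
  bad_shape <- setdiff(unique(tab$shape), c("lognormal", "normal", "uniform"))
  if (length(bad_shape) > 0) {
    stop("unknown calibration shape(s): ", paste(bad_shape, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$min_age <= 0)) {
    stop("calibration minimum ages must be positive", call. = FALSE)
  }
  if (!is.null(tree)) {
    for (cl in tab$clade_taxa) clade_mrca(tree, cl, require_monophyly = TRUE)
  }
  tab
}

#' @rdname read_calibrations
#' @param calibrations A calibration tibble.
#' @export
write_calibrations <- function(calibrations, path) {
  readr::write_tsv(calibrations, path)
  invisible(path)
}

#' Write a distance matrix as TSV
#'
#' @param d Symmetric percent distance matrix with dimnames.
#' @param path Output path.
#' @export
write_distances <- function(d, path) {
  df <- tibble::as_tibble(d, rownames = "taxon")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_distances
#' @export
read_distances <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    taxon = readr::col_character(), .default = readr::col_double()
  ))
  m <- as.matrix(df[, -1])
  rownames(m) <- df$taxon
  m
}

#' Read and write the run grid as JSON
#'
#' @param grid A [make_run_grid()] tibble.
#' @param path JSON path.
#' @export
write_run_grid <- function(grid, path) {
  jsonlite::write_json(grid, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_grid
#' @export
read_run_grid <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  purrr::map_dfr(raw, function(r) {
    tibble::tibble(
      run_id = as.integer(r$run_id),
      n_loci = as.integer(r$n_loci),
      n_outgroups = as.integer(r$n_outgroups),
      n_constraints = as.integer(r$n_constraints),
      note = r$note,
      loci = list(unlist(r$loci) %||% character()),
      taxa = list(unlist(r$taxa) %||% character()),
      calibration_clades = list(unlist(r$calibration_clades) %||% character()),
      prior_mode = r$prior_mode,
      prior_override = r$prior_override %||% NA_character_,
      approximate = isTRUE(r$approximate)
    )
  })
}

#' Write alignments as FASTA
#'
#' @param alignments Named list of `ape::DNAbin` matrices.
#' @param dir Output directory (one `<locus>.fasta` per element).
#' @return The written paths, invisibly.
#' @export
write_alignments <- function(alignments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(alignments), function(nm) {
    p <- file.path(dir, paste0(nm, ".fasta"))
    ape::write.FASTA(alignments[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_alignments
#' @export
read_alignments <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  out <- lapply(paths, function(p) as.matrix(ape::read.FASTA(p)))
  names(out) <- sub("\\.fasta$", "", basename(paths))
  out
}
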