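# Reference chronogram fixture: an aquatic-bird-like ultrametric tree whose
# calibrated clades mirror the vetted fossil constraints of the waterbird
# fossil record (crown grebes, crown Mirandornithes, stem pelican, stem
# anhinga, stem sulid, stem frigatebird, stem penguin).

node_def <- function(age, ...) list(age = age, children = list(...))
tip_def <- function(label) list(age = 0, label = label)

reference_tree_def <- function() {
  node_def(
    65,
    node_def(
      58,
      tip_def("Phaethon_lepturus"),
      node_def(
        34, # crown Mirandornithes (min 32.6)
        node_def(
          9, # crown Podicipedidae (min 8.7)
          tip_def("Podiceps_cristatus"),
          tip_def("Tachybaptus_ruficollis")
        ),
        node_def(
          4.4, # crown Phoenicopteridae
          node_def(
            2.4,
            tip_def("Phoenicopterus_roseus"),
            node_def(
              1.2,
              tip_def("Phoenicopterus_ruber"),
              tip_def("Phoenicopterus_chilensis")
            )
          ),
          node_def(
            3.1,
            tip_def("Phoeniconaias_minor"),
            node_def(
              0.5, # youngest split
              tip_def("Phoenicoparrus_andinus"),
              tip_def("Phoenicoparrus_jamesi")
            )
          )
        )
      )
    ),
    node_def(
      63, # crown Aequornithes
      node_def(
        62, # penguin-tubenose split (min 60.5)
        tip_def("Spheniscus_demersus"),
        tip_def("Procellaria_aequinoctialis")
      ),
      node_def(
        54,
        node_def(
          29, # stem Pelecanidae (min 28.3)
          tip_def("Pelecanus_occidentalis"),
          node_def(
            20,
            tip_def("Scopus_umbretta"),
            tip_def("Balaeniceps_rex")
          )
        ),
        node_def(
          52, # stem Fregatidae (min 51.8)
          tip_def("Fregata_minor"),
          node_def(
            35, # stem Sulidae (min 33.0)
            tip_def("Sula_leucogaster"),
            node_def(
              24, # stem Anhingidae (min 23.0)
              tip_def("Anhinga_melanogaster"),
              tip_def("Phalacrocorax_auritus")
            )
          )
        )
      )
    )
  )
}

def_to_newick <- function(def) {
  render <- function(node, parent_age) {
    bl <- parent_age - node$age
    if (is.null(node$children)) {
      sprintf("%s:%.10g", node$label, bl)
    } else {
      inner <- paste(
        vapply(node$children, render, character(1), parent_age = node$age),
        collapse = ","
      )
      sprintf("(%s):%.10g", inner, bl)
    }
  }
  inner <- paste(
    vapply(def$children, render, character(1), parent_age = def$age),
    collapse = ","
  )
  sprintf("(%s);", inner)
}

#' Reference chronogram of aquatic bird families
#'
#' Builds the package's fixed reference timetree: a rooted, ultrametric
#' 18-taxon chronogram (branch lengths in MY) with six flamingo species, two
#' grebes, a tropicbird, penguin, tubenose, and seven further waterbird
#' outgroups. Node ages span 0.5 MY (the youngest flamingo split) to 65 MY at
#' the root, with the penguin-tubenose divergence at 62 MY, and every clade
#' named in [default_calibrations()] is monophyletic.
#'
#' The fixture is deterministic; `seed` is accepted for pipeline uniformity
#' but does not alter it.
#'
#' @param seed Ignored (the fixture is fixed); kept so simulation pipelines
#'   can pass a seed uniformly.
#' @return An ultrametric `ape::phylo` tree with branch lengths in MY.
#' @examples
#' tr <- make_reference_chronogram()
#' max(node_ages(tr)$age) # 65
#' @export
make_reference_chronogram <- function(seed = 0L) {
  ape::read.tree(text = def_to_newick(reference_tree_def()))
}

#' Node ages of an ultrametric tree
#'
#' @param tree An ultrametric `ape::phylo` with branch lengths in time units.
#' @return A tibble with one row per internal node: `node` (ape node id),
#'   `age` (time before present) and `clade_taxa` (semicolon-joined sorted
#'   descendant tip labels).
#' @export
node_ages <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth[seq_len(ape::Ntip(tree))]) - depth
  nodes <- (ape::Ntip(tree) + 1):(ape::Ntip(tree) + tree$Nnode)
  tibble::tibble(
    node = nodes,
    age = age[nodes],
    clade_taxa = vapply(nodes, function(n) clade_key(tree, n), character(1))
  )
}

# canonical key for a node: sorted tip labels, semicolon-joined
clade_key <- function(tree, node) {
  tips <- ape::extract.clade(tree, node)$tip.label
  paste(sort(tips), collapse = ";")
}

split_taxa <- function(x) strsplit(x, ";", fixed = TRUE)[[1]]

#' Resolve a taxon set to its most recent common ancestor
#'
#' Taxa absent from the tree are dropped first (MRCA semantics are robust to
#' tip pruning). Errors if fewer than two listed taxa remain.
#'
#' @param tree An `ape::phylo`.
#' @param taxa Character vector of tip labels, or a single semicolon-joined
#'   string.
#' @param require_monophyly If `TRUE`, error unless the MRCA's descendants are
#'   exactly the retained taxa.
#' @return The ape node id of the MRCA.
#' @export
clade_mrca <- function(tree, taxa, require_monophyly = FALSE) {
  if (length(taxa) == 1 && grepl(";", taxa)) taxa <- split_taxa(taxa)
  present <- intersect(taxa, tree$tip.label)
  if (length(present) < 2) {
    stop(
      "clade cannot be resolved: fewer than two of its taxa are in the tree (",
      paste(taxa, collapse = ", "), ")",
      call. = FALSE
    )
  }
  node <- ape::getMRCA(tree, present)
  if (require_monophyly) {
    desc <- ape::extract.clade(tree, node)$tip.label
    if (!setequal(desc, present)) {
      stop(
        "clade {", paste(present, collapse = ", "),
        "} is not monophyletic on the tree",
        call. = FALSE
      )
    }
  }
  node
}

#' Vetted fossil calibration table for the reference chronogram
#'
#' The seven minimum-age constraints used throughout: crown Podicipedidae
#' (8.7 MY), stem Anhingidae (23.0), stem Pelecanidae (28.3), crown
#' Mirandornithes (32.6), stem Sulidae (33.0), stem Fregatidae (51.8) and the
#' penguin-tubenose divergence (stem Spheniscidae, 60.5). The stem-Anhingidae
#' constraint is the optional seventh: the reference analysis uses the other
#' six, and sensitivity runs add it back.
#'
#' @param include_anhinga Include the optional stem-Anhingidae row (default
#'   `FALSE`, giving the six reference constraints).
#' @return A tibble with columns `clade`, `clade_taxa` (semicolon-joined tip
#'   labels whose MRCA carries the constraint), `min_age` (MY), `shape`
#'   (prior shape for soft calibration; `"lognormal"`), and `spread` (SD of
#'   the lognormal offset, or soft maximum for uniform priors).
#' @examples
#' default_calibrations()$min_age
#' @export
default_calibrations <- function(include_anhinga = FALSE) {
  tab <- tibble::tibble(
    clade = c(
      "crown_Podicipedidae", "stem_Anhingidae", "stem_Pelecanidae",
      "crown_Mirandornithes", "stem_Sulidae", "stem_Fregatidae",
      "stem_Spheniscidae"
    ),
    clade_taxa = c(
      "Podiceps_cristatus;Tachybaptus_ruficollis",
      "Anhinga_melanogaster;Phalacrocorax_auritus",
      "Balaeniceps_rex;Pelecanus_occidentalis;Scopus_umbretta",
      paste(
        "Phoeniconaias_minor;Phoenicoparrus_andinus;Phoenicoparrus_jamesi",
        "Phoenicopterus_chilensis;Phoenicopterus_roseus;Phoenicopterus_ruber",
        "Podiceps_cristatus;Tachybaptus_ruficollis",
        sep = ";"
      ),
      "Anhinga_melanogaster;Phalacrocorax_auritus;Sula_leucogaster",
      paste(
        "Anhinga_melanogaster;Fregata_minor;Phalacrocorax_auritus",
        "Sula_leucogaster",
        sep = ";"
      ),
      "Procellaria_aequinoctialis;Spheniscus_demersus"
    ),
    min_age = c(8.7, 23.0, 28.3, 32.6, 33.0, 51.8, 60.5),
    shape = "lognormal",
    spread = 1
  )
  if (!include_anhinga) tab <- tab[tab$clade != "stem_Anhingidae", ]
  tab
}

# crown-flamingo constraint used by two sensitivity runs
flamingo_crown_calibration <- function() {
  tibble::tibble(
    clade = "crown_Phoenicopteridae",
    clade_taxa = paste(
      "Phoeniconaias_minor;Phoenicoparrus_andinus;Phoenicoparrus_jamesi",
      "Phoenicopterus_chilensis;Phoenicopterus_roseus;Phoenicopterus_ruber",
      sep = ";"
    ),
    min_age = 5.33,
    shape = "lognormal",
    spread = 1
  )
}

#' Taxon groups of the reference chronogram
#'
#' @return A named list of character vectors: `flamingos` (the six-species
#'   ingroup), `grebes` (the sister group), and `outgroups` (the ten-taxon
#'   outgroup pool).
#' @export
reference_taxa <- function() {
  list(
    flamingos = c(
      "Phoenicopterus_roseus", "Phoenicopterus_ruber",
      "Phoenicopterus_chilensis", "Phoeniconaias_minor",
      "Phoenicoparrus_andinus", "Phoenicoparrus_jamesi"
    ),
    grebes = c("Podiceps_cristatus", "Tachybaptus_ruficollis"),
    outgroups = c(
      "Phaethon_lepturus", "Spheniscus_demersus",
      "Procellaria_aequinoctialis", "Fregata_minor", "Sula_leucogaster",
      "Phalacrocorax_auritus", "Anhinga_melanogaster",
      "Pelecanus_occidentalis", "Scopus_umbretta", "Balaeniceps_rex"
    )
  )
}
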