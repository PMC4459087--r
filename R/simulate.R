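# Multi-locus sequence simulation over a chronogram. Two regimes:
# mechanistic (finite-state nucleotide evolution under a strict clock, so
# p-distances saturate naturally with depth) and stylized (pairwise distances
# drawn from a piecewise saturation model plus binomial sampling noise).

#' Default locus profiles
#'
#' Seven slow nuclear loci (five introns, one exon, one 3' UTR) of 1000 bp
#' each, plus one fast mitochondrial locus of 1500 bp treated as a single
#' partition. The mitochondrial relative rate defaults to 5x the nuclear base
#' rate so that mitochondrial distances saturate visibly within the depth of
#' the reference chronogram.
#'
#' @param mtdna_rate Relative rate multiplier for the mitochondrial locus.
#' @param ndna_length,mtdna_length Sequence lengths in bp.
#' @return A tibble with columns `name`, `genome_class` (`"nDNA"`/`"mtDNA"`),
#'   `length_bp`, `relative_rate` and `kappa` (transition/transversion rate
#'   ratio of the two-parameter substitution model).
#' @export
locus_profiles <- function(mtdna_rate = 5, ndna_length = 1000,
                           mtdna_length = 1500) {
  stopifnot(mtdna_rate > 0, ndna_length > 0, mtdna_length > 0)
  tibble::tibble(
    name = c(
      "NFKBIZ_intron6", "MB_intron2", "SLC29A4_intron8", "G3PDH_intron11",
      "TIMM17A_intron3", "ZENK_exon2", "ZENK_3UTR", "mtDNA"
    ),
    genome_class = c(rep("nDNA", 7), "mtDNA"),
    length_bp = c(rep(ndna_length, 7), mtdna_length),
    relative_rate = c(rep(1, 7), mtdna_rate),
    kappa = c(rep(2, 7), 8)
  )
}

#' Expected p-distance under the two-parameter substitution model
#'
#' Closed-form proportion of differing sites between two sequences separated
#' by `subs` expected substitutions per site under a Kimura two-parameter
#' model with transition/transversion rate ratio `kappa` (equal base
#' frequencies). With `kappa = 1` this reduces to the Jukes-Cantor form
#' `3/4 * (1 - exp(-4 subs / 3))`. Used as the independent oracle for the
#' mechanistic simulator.
#'
#' @param subs Expected substitutions per site (non-negative).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @return Expected proportion of differing sites.
#' @export
expected_p_distance <- function(subs, kappa = 1) {
  stopifnot(all(subs >= 0), kappa > 0)
  bt <- subs / (kappa + 2) # transversion-rate x time
  at <- kappa * bt
  0.75 - 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
}

#' Simulate a locus along a chronogram
#'
#' `mode = "mechanistic"` evolves nucleotide sequences site-independently
#' under a strict clock: each branch receives
#' `relative_rate * base_rate / 100 * branch duration` expected substitutions
#' per site (per lineage) under a Kimura two-parameter model, so observed
#' p-distances saturate naturally with node depth. `mode = "stylized"` skips
#' sequences entirely and draws pairwise percent distances from a
#' [saturation_model()] evaluated at the pairwise divergence times, with
#' binomial sampling noise at the locus length (`length_bp = Inf` gives the
#' exact model expectation); it returns a distance matrix.
#'
#' @param tree Ultrametric `ape::phylo` chronogram, branch lengths in MY.
#' @param locus One row of [locus_profiles()] (or a list with fields
#'   `length_bp`, `relative_rate`, `kappa`). Ignored by the stylized mode
#'   except for `length_bp`.
#' @param mode `"mechanistic"` or `"stylized"`.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param base_rate Background per-lineage rate for `relative_rate = 1`, in
#'   percent distance per MY (default 0.1, i.e. 0.2% pairwise distance per MY
#'   of divergence).
#' @param sat_model The [saturation_model()] used by the stylized mode.
#' @return Mechanistic mode: an `ape::DNAbin` alignment (taxa x sites).
#'   Stylized mode: a symmetric matrix of percent distances.
#' @examples
#' tr <- make_reference_chronogram()
#' aln <- simulate_alignment(tr, locus_profiles()[1, ], seed = 1)
#' dim(aln)
#' @export
simulate_alignment <- function(tree, locus = locus_profiles()[1, ],
                               mode = c("mechanistic", "stylized"),
                               seed = NULL, base_rate = 0.1,
                               sat_model = saturation_model()) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  locus <- as.list(locus)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "stylized") {
    return(stylized_distances(tree, sat_model, length_bp = locus$length_bp))
  }
  if (locus$length_bp <= 0) stop("sequence length must be positive", call. = FALSE)
  if (locus$relative_rate < 0 || base_rate < 0) {
    stop("substitution rates must be non-negative", call. = FALSE)
  }
  scaled <- tree
  scaled$edge.length <- tree$edge.length * locus$relative_rate * base_rate / 100
  kappa <- if (is.null(locus$kappa)) 1 else locus$kappa
  sim <- phangorn::simSeq(
    scaled,
    l = locus$length_bp,
    Q = c(1, kappa, 1, 1, kappa, 1),
    bf = rep(0.25, 4)
  )
  as.matrix(ape::as.DNAbin(sim))
}

#' Stylized pairwise distances from a saturation model
#'
#' Evaluates a [saturation_model()] at each pair's divergence time (the age of
#' the pair's MRCA) and, for finite `length_bp`, adds binomial sampling noise:
#' the observed distance is `Binomial(length_bp, d/100) / length_bp * 100`.
#'
#' @inheritParams simulate_alignment
#' @param model A [saturation_model()].
#' @param length_bp Locus length controlling the noise; `Inf` for the exact
#'   expectation.
#' @return Symmetric matrix of percent distances with zero diagonal, taxon
#'   labels as dimnames.
#' @export
stylized_distances <- function(tree, model = saturation_model(),
                               length_bp = Inf, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(seed)) set.seed(seed)
  split_times <- ape::cophenetic.phylo(tree) / 2
  d <- split_times
  d[] <- expected_distance(model, as.vector(split_times))
  if (is.finite(length_bp)) {
    up <- upper.tri(d)
    p <- pmin(d[up] / 100, 1)
    obs <- stats::rbinom(sum(up), size = length_bp, prob = p) / length_bp * 100
    d[up] <- obs
    d[lower.tri(d)] <- t(d)[lower.tri(d)]
  }
  diag(d) <- 0
  d
}

#' Simulate the full multi-locus dataset
#'
#' Runs [simulate_alignment()] mechanistically for every row of `loci` over
#' one chronogram, with a deterministic per-locus RNG stream derived from
#' `seed`.
#'
#' @inheritParams simulate_alignment
#' @param loci A [locus_profiles()]-shaped tibble.
#' @param seed Integer seed for the whole bundle.
#' @return Named list of `ape::DNAbin` alignments, one per locus.
#' @export
simulate_dataset <- function(tree, loci = locus_profiles(), seed = 0L,
                             base_rate = 0.1) {
  set.seed(seed)
  out <- lapply(seq_len(nrow(loci)), function(i) {
    simulate_alignment(tree, loci[i, ], mode = "mechanistic",
                       base_rate = base_rate)
  })
  names(out) <- loci$name
  out
}

#' Pairwise percent distance matrix from an alignment
#'
#' @param aln An `ape::DNAbin` alignment (or character matrix, taxa in rows).
#' @param correction `"raw"` for uncorrected p-distances (default; residual
#'   homoplasy is deliberately left in) or `"JC69"` for Jukes-Cantor-corrected
#'   distances.
#' @return Symmetric matrix of percent distances.
#' @export
p_distance_matrix <- function(aln, correction = c("raw", "JC69")) {
  correction <- match.arg(correction)
  if (!inherits(aln, "DNAbin")) aln <- ape::as.DNAbin(aln)
  d <- ape::dist.dna(aln, model = correction, pairwise.deletion = FALSE)
  as.matrix(d) * 100
}
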