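# Sensitivity harness: the grid of comparative dating runs (calibration,
# locus, taxon and prior-shape variants around a reference analysis), the
# sweep executing them, and deviation summaries for a representative young
# and old node.

#' The 45-run sensitivity grid
#'
#' Machine-readable table of the comparative dating runs: a reference
#' analysis (run 3: seven nuclear loci, eight outgroups, six calibrations)
#' and variants that alter locus sampling, genome class (mtDNA), taxon and
#' outgroup sampling, the number/age of calibrations, and prior shape, one
#' factor at a time. Loci and taxa dropped by a variant are chosen
#' deterministically (alphabetically). Runs probing Bayesian-only machinery
#' (joint prior with zero constraints; unpartitioned likelihood; soft prior
#' shapes) are marked `approximate`; zero-constraint runs cannot be dated by
#' a calibrated clock and are skipped by [run_sweep()].
#'
#' @return A tibble with one row per run: `run_id`, `n_loci`, `n_outgroups`,
#'   `n_constraints`, `note`, list-columns `loci`, `taxa`,
#'   `calibration_clades`, plus `prior_mode` (`"point_min"`/`"soft"`),
#'   `prior_override` (`NA`, `"uniform_wide"` or `"lognormal_wide"`) and
#'   `approximate`.
#' @examples
#' grid <- make_run_grid()
#' nrow(grid) # 45
#' @export
make_run_grid <- function() {
  taxa <- reference_taxa()
  ndna <- sort(setdiff(locus_profiles()$name, "mtDNA"))
  loci_n <- function(k) ndna[seq_len(k)]
  # outgroup inclusion priority: the eight reference outgroups, then the
  # tropicbird, then the shoebill
  out_priority <- c(
    "Spheniscus_demersus", "Procellaria_aequinoctialis", "Fregata_minor",
    "Sula_leucogaster", "Phalacrocorax_auritus", "Anhinga_melanogaster",
    "Pelecanus_occidentalis", "Scopus_umbretta", "Phaethon_lepturus",
    "Balaeniceps_rex"
  )
  taxa_for <- function(n_out, flamingos = taxa$flamingos, grebes = taxa$grebes) {
    c(flamingos, grebes, out_priority[seq_len(n_out)])
  }
  flam2 <- c("Phoenicopterus_chilensis", "Phoeniconaias_minor") # one per genus

  cal6 <- default_calibrations(include_anhinga = FALSE)$clade
  young2 <- c("crown_Podicipedidae", "crown_Mirandornithes")
  old4 <- c("crown_Mirandornithes", "stem_Sulidae", "stem_Fregatidae",
            "stem_Spheniscidae")
  deep_one <- c(
    penguin = "stem_Spheniscidae", fregatebird = "stem_Fregatidae",
    gannet = "stem_Sulidae", pelican = "stem_Pelecanidae"
  )

  row <- function(run_id, loci, n_out, cals, note, taxa_set = taxa_for(n_out),
                  prior_mode = "point_min", prior_override = NA_character_,
                  approximate = FALSE) {
    tibble::tibble(
      run_id = run_id,
      n_loci = length(loci),
      n_outgroups = n_out,
      n_constraints = length(cals),
      note = note,
      loci = list(loci),
      taxa = list(taxa_set),
      calibration_clades = list(cals),
      prior_mode = prior_mode,
      prior_override = prior_override,
      approximate = approximate
    )
  }

  excl <- function(nm) setdiff(ndna, nm)
  grid <- dplyr::bind_rows(
    row(1, ndna, 8, character(), "Testing joint prior", approximate = TRUE),
    row(2, loci_n(4), 10, character(), "Testing joint prior", approximate = TRUE),
    row(3, ndna, 8, cal6, "Reference run nDNA"),
    row(4, c(ndna, "mtDNA"), 8, cal6, "See 3, +mtDNA"),
    row(5, "mtDNA", 8, cal6, "mtDNA only"),
    row(6, ndna, 8, cal6, "See 3, 4 of 6 flamingo species excluded",
        taxa_set = taxa_for(8, flamingos = flam2)),
    row(7, loci_n(4), 10, cal6, "See 3, 4 loci only"),
    row(8, loci_n(4), 10, c(cal6, "stem_Anhingidae"),
        "See 7, anhinga constraint added"),
    row(9, loci_n(5), 9, cal6, "See 3, 5 loci only"),
    row(10, loci_n(5), 9, c(cal6, "stem_Anhingidae"),
        "See 9, anhinga constraint added"),
    row(11, loci_n(6), 8, cal6, "See 3, 6 loci only"),
    row(12, loci_n(4), 10, young2, "See 7, youngest constraints only"),
    row(13, loci_n(5), 9, young2, "See 9, youngest constraints only"),
    row(14, loci_n(6), 8, young2, "See 11, youngest constraints only"),
    row(15, ndna, 8, young2, "See 3, youngest constraints only"),
    row(16, loci_n(4), 3, young2, "See 12, reduced outgroup sampling"),
    row(17, loci_n(5), 3, young2, "See 13, reduced outgroup sampling"),
    row(18, loci_n(6), 3, young2, "See 14, reduced outgroup sampling"),
    row(19, ndna, 3, young2, "See 15, reduced outgroup sampling"),
    dplyr::bind_rows(lapply(1:6, function(i) {
      row(19 + i, excl(ndna[i]), 8, cal6,
          paste0("See 3, 1 locus excluded (", ndna[i], ")"))
    })),
    row(26, ndna, 8, cal6, "See 3, constraint maxima increased to 65 or 30",
        prior_mode = "soft", prior_override = "uniform_wide", approximate = TRUE),
    row(27, ndna, 8, cal6, "See 26, uniform prior distribution",
        prior_mode = "soft", prior_override = "uniform_wide", approximate = TRUE),
    row(28, ndna, 8, cal6, "See 26, 95% prior range at 65 or 30",
        prior_mode = "soft", prior_override = "lognormal_wide", approximate = TRUE),
    row(29, ndna, 8, cal6, "See 3, loci unpartitioned", approximate = TRUE),
    row(30, ndna, 8, c(cal6, "crown_Phoenicopteridae"),
        "See 3, + min Phoenicopteridae = 5.33 constraint"),
    row(31, ndna, 8, c(young2, "crown_Phoenicopteridae"),
        "See 15, + min Phoenicopteridae = 5.33 constraint"),
    row(32, ndna, 8, setdiff(cal6, c("crown_Podicipedidae", "crown_Mirandornithes")),
        "See 3, sistergroup (grebe) taxa excluded",
        taxa_set = taxa_for(8, grebes = character())),
    row(33, ndna, 8, setdiff(cal6, "stem_Spheniscidae"),
        "See 3, stem penguin constraint excluded"),
    row(34, ndna, 8, setdiff(cal6, "stem_Fregatidae"),
        "See 3, stem fregatebird constraint excluded"),
    row(35, ndna, 8, setdiff(cal6, "stem_Sulidae"),
        "See 3, stem gannet constraint excluded"),
    row(36, ndna, 8, setdiff(cal6, "stem_Pelecanidae"),
        "See 3, stem pelican constraint excluded"),
    row(37, ndna, 8, old4, "See 3, oldest constraints only"),
    dplyr::bind_rows(lapply(seq_along(deep_one), function(i) {
      row(37 + i, ndna, 8, c(young2, deep_one[[i]]),
          paste0("See 15, stem ", names(deep_one)[i], " constraint added"))
    })),
    dplyr::bind_rows(lapply(seq_along(deep_one), function(i) {
      row(41 + i, ndna, 8, deep_one[[i]],
          paste0("See 3, stem ", names(deep_one)[i], " constraint only"))
    }))
  )
  grid
}

# full calibration pool the grid's clade references resolve against
grid_calibration_pool <- function() {
  dplyr::bind_rows(
    default_calibrations(include_anhinga = TRUE),
    flamingo_crown_calibration()
  )
}

apply_prior_override <- function(cals, override) {
  if (is.na(override)) return(cals)
  if (override == "uniform_wide") {
    cals$shape <- "uniform"
    cals$spread <- ifelse(cals$clade == "crown_Podicipedidae", 30, 65)
  } else if (override == "lognormal_wide") {
    cals$shape <- "lognormal"
    cals$spread <- 2
  }
  cals
}

#' Execute the sensitivity grid and summarise deviations from a reference run
#'
#' Dates every run of the grid with [date_tree()] on its own locus/taxon/
#' calibration subset, then computes, for every internal node of the reference
#' run that is still resolvable in a given run (MRCA of the shared taxa), the
#' percent deviation of that run's age from the reference age. Runs with no
#' constraints are skipped with a message.
#'
#' @param grid A [make_run_grid()] tibble (or subset of its rows).
#' @param data Named list of per-locus data keyed by locus name: `ape::DNAbin`
#'   alignments or percent distance matrices. A single unnamed distance matrix
#'   is accepted and reused for every locus (stylized data has no locus
#'   structure).
#' @param tree The full reference chronogram topology (runs prune it).
#' @param reference_id Run id of the reference analysis (default 3).
#' @param calibration_pool Calibration table the grid's clade names resolve
#'   against (defaults to all seven fossil constraints plus the optional crown
#'   flamingo constraint).
#' @param tolerance Relative tolerance for the deviation class (default 0.05).
#' @param bootstrap_reps Bootstrap replicates per run (default 0: point
#'   estimates only, as the sweep compares points).
#' @param seed Integer seed (used only when `bootstrap_reps > 0`).
#' @return A tibble of per-node deviation records: `run_id`, `note`,
#'   `approximate`, `clade_taxa` (reference-node key), `run_age`, `ref_age`,
#'   `deviation_pct`, `class`.
#' @export
run_sweep <- function(grid, data, tree, reference_id = 3,
                      calibration_pool = grid_calibration_pool(),
                      tolerance = 0.05, bootstrap_reps = 0, seed = NULL) {
  stopifnot(reference_id %in% grid$run_id)
  if (is.matrix(data) && is.numeric(data)) {
    mat <- data
    data <- setNames(
      rep(list(mat), nrow(locus_profiles())), locus_profiles()$name
    )
  }
  if (!is.null(seed)) set.seed(seed)

  run_one <- function(i) {
    cfg <- grid[i, ]
    cals <- calibration_pool[
      match(cfg$calibration_clades[[1]], calibration_pool$clade),
    ]
    if (nrow(cals) == 0) return(NULL)
    cals <- apply_prior_override(cals, cfg$prior_override)
    keep <- intersect(tree$tip.label, cfg$taxa[[1]])
    run_tree <- ape::keep.tip(tree, keep)
    missing_loci <- setdiff(cfg$loci[[1]], names(data))
    if (length(missing_loci) > 0) {
      stop("grid references loci absent from data: ",
           paste(missing_loci, collapse = ", "), call. = FALSE)
    }
    run_data <- lapply(data[cfg$loci[[1]]], function(x) {
      if (inherits(x, "DNAbin")) x[keep, ] else x[keep, keep]
    })
    dt <- date_tree(run_tree, run_data, cals, mode = cfg$prior_mode,
                    bootstrap_reps = bootstrap_reps)
    list(tree = run_tree, estimates = dt$estimates)
  }

  ref <- run_one(which(grid$run_id == reference_id))
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cfg <- grid[i, ]
    if (length(cfg$calibration_clades[[1]]) == 0) {
      message("run ", cfg$run_id, " has no constraints; skipped (", cfg$note, ")")
      return(NULL)
    }
    res <- run_one(i)
    matched <- purrr::map_dfr(seq_len(nrow(ref$estimates)), function(j) {
      ref_taxa <- split_taxa(ref$estimates$clade_taxa[j])
      shared <- intersect(ref_taxa, res$tree$tip.label)
      if (length(shared) < 2) return(NULL)
      node <- ape::getMRCA(res$tree, shared)
      tibble::tibble(
        clade_taxa = ref$estimates$clade_taxa[j],
        ref_age = ref$estimates$point_age[j],
        run_age = res$estimates$point_age[match(node, res$estimates$node)]
      )
    })
    dev <- ifelse(matched$ref_age > 0,
                  (matched$run_age - matched$ref_age) / matched$ref_age * 100, 0)
    tibble::tibble(
      run_id = cfg$run_id,
      note = cfg$note,
      approximate = cfg$approximate,
      clade_taxa = matched$clade_taxa,
      run_age = matched$run_age,
      ref_age = matched$ref_age,
      deviation_pct = dev,
      class = deviation_class(dev, tolerance)
    )
  })
  out
}

#' Default representative node keys
#'
#' The young node is crown Phoenicopteridae; the old node is the
#' penguin-tubenose divergence.
#' @return Named list with `young` and `old` clade keys.
#' @export
representative_nodes <- function() {
  tr <- make_reference_chronogram()
  taxa <- reference_taxa()
  list(
    young = clade_key(tr, clade_mrca(tr, taxa$flamingos)),
    old = clade_key(tr, clade_mrca(
      tr, c("Spheniscus_demersus", "Procellaria_aequinoctialis")
    ))
  )
}

#' Paired young/old node ages across runs
#'
#' One row per run with the estimated age of a representative young and old
#' node; runs in which either node is unresolvable are omitted with a message.
#'
#' @param summaries Output of [run_sweep()].
#' @param young,old Clade keys (semicolon-joined taxa) of the two nodes;
#'   default [representative_nodes()].
#' @param reference_id Run id flagged as the reference.
#' @return Tibble with `run_id`, `note`, `young_age`, `old_age`,
#'   `is_reference`.
#' @export
scatter_pairs <- function(summaries, young = representative_nodes()$young,
                          old = representative_nodes()$old, reference_id = 3) {
  match_node <- function(df, key) {
    # a run's node keyed by the reference clade is matched on the shared taxa
    hit <- df[df$clade_taxa == key, ]
    if (nrow(hit) == 0) NA_real_ else hit$run_age[1]
  }
  out <- summaries |>
    dplyr::group_by(.data$run_id, .data$note) |>
    dplyr::summarise(
      young_age = match_node(dplyr::pick(dplyr::everything()), young),
      old_age = match_node(dplyr::pick(dplyr::everything()), old),
      .groups = "drop"
    ) |>
    dplyr::mutate(is_reference = .data$run_id == reference_id)
  dropped <- out$run_id[is.na(out$young_age) | is.na(out$old_age)]
  if (length(dropped) > 0) {
    message("runs omitted (node unresolvable): ", paste(dropped, collapse = ", "))
  }
  out[!is.na(out$young_age) & !is.na(out$old_age), ]
}

#' Default factor grouping for the deviation summary table
#'
#' Maps grid runs to the seven sensitivity factors, each run paired with the
#' baseline it isolates (so, e.g., reduced-outgroup runs are compared against
#' their full-outgroup counterparts with identical loci and constraints, not
#' against the reference).
#'
#' @return Tibble with columns `factor_name`, `run_id`, `baseline_id`.
#' @export
default_factor_grouping <- function() {
  g <- function(factor_name, run_id, baseline_id) {
    tibble::tibble(factor_name = factor_name, run_id = run_id,
                   baseline_id = baseline_id)
  }
  dplyr::bind_rows(
    g("Taxon sampling", 6, 3),
    g("Outgroup sampling", 16:19, 12:15),
    g("Locus sampling", c(7, 9, 11, 20:25), 3),
    g("Genome sampling", c(4, 5), 3),
    g("Calibration sampling-1", c(8, 10, 30, 33:36, 38:41), c(7, 9, 3, 3, 3, 3, 3, 15, 15, 15, 15)),
    g("Calibration sampling-2", c(12:15, 37, 42:45), c(7, 9, 11, 3, 3, 3, 3, 3, 3)),
    g("Calibration sampling-3", 26:28, 3)
  )
}

#' Per-factor deviation summary for a young and old node
#'
#' For each sensitivity factor, reports the maximum-magnitude percent
#' deviation (and its sign class) of the designated young and old node across
#' the factor's run/baseline pairs.
#'
#' @inheritParams scatter_pairs
#' @param grouping A [default_factor_grouping()]-shaped tibble.
#' @param tolerance Relative tolerance for the class.
#' @return Tibble with one row per factor: `factor_name`, `young_class`,
#'   `young_max_dev_pct`, `old_class`, `old_max_dev_pct`.
#' @export
summarize_table2 <- function(summaries, grouping = default_factor_grouping(),
                             young = representative_nodes()$young,
                             old = representative_nodes()$old,
                             tolerance = 0.05) {
  if (nrow(grouping) == 0) stop("empty factor grouping", call. = FALSE)
  age_of <- function(run, key) {
    hit <- summaries[summaries$run_id == run & summaries$clade_taxa == key, ]
    if (nrow(hit) == 0) NA_real_ else hit$run_age[1]
  }
  pair_dev <- function(run, base, key) {
    a <- age_of(run, key); b <- age_of(base, key)
    if (is.na(a) || is.na(b) || b == 0) NA_real_ else (a - b) / b * 100
  }
  purrr::map_dfr(unique(grouping$factor_name), function(f) {
    rows <- grouping[grouping$factor_name == f, ]
    yd <- mapply(pair_dev, rows$run_id, rows$baseline_id, MoreArgs = list(key = young))
    od <- mapply(pair_dev, rows$run_id, rows$baseline_id, MoreArgs = list(key = old))
    pick_max <- function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) return(NA_real_)
      v[which.max(abs(v))]
    }
    ym <- pick_max(yd); om <- pick_max(od)
    tibble::tibble(
      factor_name = f,
      young_class = deviation_class(ym %||% NA_real_, tolerance),
      young_max_dev_pct = ym,
      old_class = deviation_class(om %||% NA_real_, tolerance),
      old_max_dev_pct = om
    )
  })
}
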