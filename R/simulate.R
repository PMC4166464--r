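#' Locus settings for the simulator
#'
#' @param name locus name.
#' @param n_sites alignment length in bp.
#' @param rate substitution rate (expected substitutions per site per unit
#'   of tree time).
#' @param model \code{"JC"} or \code{"HKY"}.
#' @param kappa transition/transversion rate ratio for HKY.
#' @param base_freq equilibrium base frequencies (A, C, G, T).
#' @param indel_events expected number of species-level indel events.
#' @param missing_fraction fraction of cells replaced by missing states.
#' @param truncation_fraction fraction of specimens reduced to partial
#'   sequences (exercising the coverage filter).
#' @export
sim_locus <- function(name, n_sites, rate, model = c("JC", "HKY"),
                      kappa = 4, base_freq = rep(0.25, 4),
                      indel_events = 1, missing_fraction = 0.005,
                      truncation_fraction = 0.05) {
  model <- match.arg(model)
  stopifnot(n_sites >= 1, rate >= 0, kappa > 0,
            abs(sum(base_freq) - 1) < 1e-8,
            indel_events >= 0, missing_fraction >= 0, missing_fraction < 1,
            truncation_fraction >= 0, truncation_fraction < 1)
  list(name = name, n_sites = n_sites, rate = rate, model = model,
       kappa = kappa, base_freq = base_freq, indel_events = indel_events,
       missing_fraction = missing_fraction,
       truncation_fraction = truncation_fraction)
}

#' Simulation configuration
#'
#' The defaults emulate a three-locus design with contrasting rates: a slow
#' ~1500 bp ribosomal-like locus, a medium ~2000 bp ribosomal-like locus and
#' a fast, saturating ~330 bp coding locus, over 6 species of 8 specimens
#' each.  The species tree is a pure-birth tree rescaled to depth 1 and
#' conditioned on a minimum between-species divergence of
#' \code{min_split_frac}; within-species genealogies are coalescent trees
#' rescaled to \code{within_depth}, so between/within divergence is at least
#' \code{min_split_frac / within_depth} (10x with the defaults).
#'
#' @param n_species number of species.
#' @param specimens_per_species scalar or per-species vector (1 to ~45).
#' @param loci list of [sim_locus()] settings.
#' @param species_depth root depth of the species tree (time units).
#' @param min_split_frac minimum pairwise species divergence, as a fraction
#'   of \code{species_depth}.
#' @param within_depth height of within-species genealogies (time units).
#' @param seed integer seed; the seed fully determines the output.
#' @export
sim_config <- function(n_species = 6,
                       specimens_per_species = 8,
                       loci = list(
                         sim_locus("slow", 1502, 0.02),
                         sim_locus("medium", 2009, 0.05),
                         sim_locus("fast", 328, 0.40, model = "HKY")
                       ),
                       species_depth = 1,
                       min_split_frac = 0.4,
                       within_depth = 0.04,
                       seed = 1L) {
  if (n_species < 1) stop("need at least one species")
  specimens_per_species <- rep_len(specimens_per_species, n_species)
  stopifnot(all(specimens_per_species >= 1), species_depth > 0,
            within_depth >= 0, min_split_frac > 0, min_split_frac <= 1)
  structure(list(n_species = n_species,
                 specimens_per_species = as.integer(specimens_per_species),
                 loci = loci, species_depth = species_depth,
                 min_split_frac = min_split_frac,
                 within_depth = within_depth, seed = as.integer(seed)),
            class = "sim_config")
}

# pure-birth species tree of depth `depth` with all splits deeper than
# min_frac * depth (rejection sampled)
draw_species_tree <- function(n, depth, min_frac, labels) {
  if (n == 1L) stop("species tree needs >= 2 species")
  for (try in 1:2000) {
    phy <- ape::rphylo(n, birth = 1, death = 0)
    h <- max(ape::node.depth.edgelength(phy))
    phy$edge.length <- phy$edge.length * depth / h
    div <- ape::cophenetic.phylo(phy) / 2
    if (min(div[upper.tri(div)]) >= min_frac * depth) {
      phy$tip.label <- labels
      return(phy)
    }
  }
  stop("could not draw a species tree satisfying min_split_frac")
}

# graft within-species coalescent subtrees onto the species tree tips,
# keeping the composite tree ultrametric; returns an ape::phylo
graft_genealogy <- function(sp_tree, members, within_depth) {
  tmp <- sp_tree
  tmp$tip.label <- sprintf("ZZSP%04dZZ", seq_along(tmp$tip.label))
  nwk <- ape::write.tree(tmp)
  tip_edge <- match(seq_along(tmp$tip.label), tmp$edge[, 2])
  for (i in seq_along(members)) {
    ids <- members[[i]]
    len <- tmp$edge.length[tip_edge[i]]
    if (length(ids) == 1L) {
      rep_str <- paste0(ids, ":", format(len + within_depth, digits = 12))
    } else {
      sub <- ape::rcoal(length(ids), tip.label = ids)
      h <- max(ape::node.depth.edgelength(sub))
      if (within_depth > 0 && h > 0) {
        sub$edge.length <- sub$edge.length * within_depth / h
      } else {
        sub$edge.length <- sub$edge.length * 0
      }
      subnwk <- sub("; *$", "", ape::write.tree(sub))
      rep_str <- paste0(subnwk, ":",
                        format(max(len - within_depth, 0), digits = 12))
    }
    nwk <- sub(sprintf("ZZSP%04dZZ:[0-9.eE+-]+", i), rep_str, nwk)
  }
  ape::read.tree(text = nwk)
}

simulate_locus_seqs <- function(gene_tree, locus) {
  phy <- gene_tree
  phy$edge.length <- phy$edge.length * locus$rate
  Q <- if (locus$model == "HKY") {
    c(1, locus$kappa, 1, 1, locus$kappa, 1)  # ac ag at cg ct gt
  } else rep(1, 6)
  bf <- if (locus$model == "HKY") locus$base_freq else rep(0.25, 4)
  sim <- phangorn::simSeq(phy, l = locus$n_sites, type = "DNA",
                          bf = bf, Q = Q)
  m <- toupper(as.character(sim))
  m[, , drop = FALSE]
}

apply_indels <- function(m, members, locus) {
  n_events <- rpois(1, locus$indel_events)
  L <- ncol(m)
  for (ev in seq_len(n_events)) {
    sp <- sample(length(members), 1)
    start <- sample(L, 1)
    len <- 1 + rgeom(1, 0.35)
    cols <- start:min(L, start + len - 1)
    rows <- rownames(m) %in% members[[sp]]
    if (runif(1) < 0.5) {
      m[!rows, cols] <- "-"   # insertion unique to this species
    } else {
      m[rows, cols] <- "-"    # deletion in this species
    }
  }
  m
}

apply_missing <- function(m, locus) {
  if (locus$missing_fraction > 0) {
    hit <- runif(length(m)) < locus$missing_fraction
    m[hit] <- "?"
  }
  n_trunc <- rbinom(1, nrow(m), locus$truncation_fraction)
  if (n_trunc > 0) {
    rows <- sample(nrow(m), n_trunc)
    for (r in rows) {
      tlen <- floor(runif(1, 0.55, 0.8) * ncol(m))
      if (runif(1) < 0.5) m[r, seq_len(tlen)] <- "?"
      else m[r, (ncol(m) - tlen + 1):ncol(m)] <- "?"
    }
  }
  m
}

#' Simulate a multilocus dataset with known species structure
#'
#' Draws a pure-birth species tree, independent within-species coalescent
#' genealogies per locus, evolves sequences column-independently under the
#' configured substitution model, and adds species-level indel blocks,
#' missing cells and truncated (partial) specimens.  True per-locus gene
#' trees are emitted as fully supported trees, so every pipeline stage can
#' be checked against ground truth.
#'
#' @param config a [sim_config()].
#' @param species_tree optional fixed species tree ([ape::phylo], tip
#'   labels \code{sp1..spk}) overriding the pure-birth draw.
#' @return list with elements \code{dataset} (a \code{multilocus_dataset})
#'   and \code{truth} (list: \code{partition} tibble, \code{species_tree},
#'   \code{gene_trees}, \code{config}).
#' @export
simulate_dataset <- function(config = sim_config(), species_tree = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- config$n_species
  species <- paste0("sp", seq_len(k))
  members <- purrr::map(seq_len(k), function(i) {
    sprintf("%s_%02d", species[i], seq_len(config$specimens_per_species[i]))
  })
  names(members) <- species

  sp_tree <- if (!is.null(species_tree)) species_tree
    else draw_species_tree(k, config$species_depth, config$min_split_frac,
                           species)

  gene_trees <- list()
  alignments <- list()
  for (locus in config$loci) {
    gt <- graft_genealogy(sp_tree, members, config$within_depth)
    m <- simulate_locus_seqs(gt, locus)
    m <- apply_indels(m, members, locus)
    m <- apply_missing(m, locus)
    alignments[[locus$name]] <- dna_alignment(m, locus_name = locus$name)
    gt$node.label <- rep("100", gt$Nnode)
    # true trees are reported like estimated gene trees: branch lengths in
    # expected substitutions per site
    gt$edge.length <- gt$edge.length * locus$rate
    gene_trees[[locus$name]] <- as_support_tree(gt, "bootstrap_percent")
  }

  partition <- tibble::tibble(
    specimen_id = unlist(members),
    group = rep(species, lengths(members))
  )
  specimens <- tibble::tibble(
    specimen_id = partition$specimen_id,
    clade = partition$group,
    locality = "SIM",
    is_outgroup = FALSE,
    type_status = ifelse(
      partition$specimen_id %in% vapply(members, `[`, "", 1L),
      "holotype", "none")
  )
  dataset <- suppressWarnings(
    assemble_dataset(alignments, specimens, gene_trees))
  list(dataset = dataset,
       truth = list(partition = partition, species_tree = sp_tree,
                    gene_trees = gene_trees, config = config))
}

#' Engineered hard-case datasets
#'
#' Builds datasets that trigger known failure modes of distance- and
#' network-based delimitation, each annotated with the expected pipeline
#' behaviour:
#' \describe{
#'   \item{shared_haplotype}{two true species share one haplotype at the
#'     slow locus (all of species 2 carries species 1's first haplotype):
#'     one slow-locus network contains both species, while the fast locus
#'     separates them.}
#'   \item{singleton_species}{the last species has a single specimen: its
#'     intra-group distance is undefined (flagged), and its status is
#'     capped at candidate.}
#'   \item{saturated_locus}{the fast locus rate is quadrupled: its
#'     p-distance vs patristic-distance slope drops below the slow locus'
#'     slope.}
#'   \item{shallow_split}{two species diverge barely beyond the
#'     within-species scale: slow loci merge them into one group.}
#' }
#'
#' @param scenario one of the names above.
#' @param config base configuration.
#' @return as [simulate_dataset()], with \code{truth$scenario} and
#'   \code{truth$expected} annotations added.
#' @export
make_hard_case <- function(scenario = c("shared_haplotype",
                                        "singleton_species",
                                        "saturated_locus",
                                        "shallow_split"),
                           config = sim_config()) {
  scenario <- match.arg(scenario)
  expected <- NULL
  species_tree <- NULL
  if (scenario == "singleton_species") {
    spp <- rep_len(config$specimens_per_species, config$n_species)
    spp[config$n_species] <- 1L
    config$specimens_per_species <- spp
    expected <- list(singleton = paste0("sp", config$n_species))
  } else if (scenario == "saturated_locus") {
    idx <- which(vapply(config$loci, function(l) l$name, "") == "fast")
    if (!length(idx)) stop("saturated_locus scenario needs a 'fast' locus")
    config$loci[[idx]]$rate <- config$loci[[idx]]$rate * 4
    expected <- list(fast_locus = "fast", slow_locus = "slow")
  } else if (scenario == "shallow_split") {
    # fixed balanced tree with one cherry just above the within-species scale
    shallow <- 2.5 * config$within_depth
    d <- config$species_depth
    nwk <- sprintf(
      "(((sp1:%g,sp2:%g):%g,(sp3:%g,sp4:%g):%g):%g,(sp5:%g,sp6:%g):%g);",
      0.5 * d, 0.5 * d, 0.3 * d, 0.5 * d, 0.5 * d, 0.3 * d, 0.2 * d,
      shallow, shallow, d - shallow)
    species_tree <- ape::read.tree(text = nwk)
    config$n_species <- 6L
    config$specimens_per_species <- rep_len(config$specimens_per_species, 6L)
    expected <- list(merged_pair = c("sp5", "sp6"))
  }
  sim <- simulate_dataset(config, species_tree = species_tree)
  if (scenario == "shared_haplotype") {
    slow <- sim$dataset$loci[[1]]
    part <- sim$truth$partition
    a_first <- part$specimen_id[part$group == "sp1"][1]
    b_ids <- part$specimen_id[part$group == "sp2"]
    m <- unclass(slow)
    m[b_ids, ] <- matrix(m[a_first, ], nrow = length(b_ids),
                         ncol = ncol(m), byrow = TRUE)
    sim$dataset$loci[[1]] <- dna_alignment(m, locus_name = locus_name(slow))
    expected <- list(merged_species = c("sp1", "sp2"),
                     slow_locus = names(sim$dataset$loci)[1],
                     split_by = "fast")
  }
  sim$truth$scenario <- scenario
  sim$truth$expected <- expected
  sim
}
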