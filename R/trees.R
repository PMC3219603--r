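## Rooted-tree helpers shared across modules. Trees are ape::phylo objects;
## a "timetree" additionally carries node ages in Ma (tips at 0) and, when
## simulated, per-edge lognormal rate multipliers.

#' List the tip labels descending from each node
#'
#' @param tree A rooted `phylo`.
#' @return Named list (by node number) of character vectors of tip labels.
#' @export
node_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1]; ch <- po[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  names(sets) <- as.character(seq_len(nn))
  sets
}

#' Find the MRCA node of a set of taxa
#'
#' @param tree Rooted `phylo`.
#' @param taxa Character vector of tip labels (length >= 1).
#' @return Node number.
#' @export
mrca_node <- function(tree, taxa) {
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss)) abort(paste("taxa not in tree:", paste(miss, collapse = ", ")))
  if (length(taxa) == 1L) return(match(taxa, tree$tip.label))
  ape::getMRCA(tree, taxa)
}

#' Does a taxon set form a clade of the tree?
#' @inheritParams mrca_node
#' @return Logical.
#' @export
is_clade <- function(tree, taxa) {
  node <- mrca_node(tree, taxa)
  sets <- node_tip_sets(tree)
  setequal(sets[[node]], taxa)
}

#' Attach node ages to a rooted topology
#'
#' @param tree Rooted `phylo`.
#' @param ages Numeric vector of ages in Ma for all nodes (tips first, ape
#'   numbering), or a named list mapping are resolved with [mrca_node()] via
#'   `age_table`.
#' @param age_table Optional tibble with list-column `taxa` and column
#'   `age_ma`; each row sets the age of `mrca_node(tree, taxa)`. Tip ages
#'   default to 0.
#' @return A `timetree`: `phylo` with `node.ages` and edge lengths in Ma.
#' @export
timetree <- function(tree, ages = NULL, age_table = NULL) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  if (is.null(ages)) {
    ages <- numeric(nn)
    for (i in seq_len(nrow(age_table))) {
      ages[mrca_node(tree, age_table$taxa[[i]])] <- age_table$age_ma[i]
    }
  }
  if (length(ages) != nn) abort("ages must cover every node")
  bad <- ages[tree$edge[, 1]] <= ages[tree$edge[, 2]]
  if (any(bad)) abort("parent ages must exceed child ages")
  tree$node.ages <- ages
  tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  class(tree) <- unique(c("timetree", class(tree)))
  tree
}

#' Recover node ages from an ultrametric tree with edge lengths
#' @param tree Rooted `phylo` with edge lengths in Ma.
#' @return A `timetree`.
#' @export
as_timetree <- function(tree) {
  if (inherits(tree, "timetree") && !is.null(tree$node.ages)) return(tree)
  depths <- ape::node.depth.edgelength(tree)
  ages <- max(depths) - depths
  ages[abs(ages) < 1e-9] <- 0
  timetree(tree, ages = ages)
}

#' Build a rooted tree from a laminar family of clades
#'
#' Given pairwise nested-or-disjoint taxon sets, returns the rooted tree whose
#' internal nodes are exactly those sets (plus the root spanning `taxa`), with
#' polytomies where structure is unresolved.
#'
#' @param clades List of character vectors (each a proper, non-singleton
#'   subset of `taxa`, or the full set which is absorbed into the root).
#' @param taxa All tip labels, in display order.
#' @return Rooted `phylo`.
#' @export
tree_from_clades <- function(clades, taxa) {
  clades <- unique(lapply(clades, function(s) taxa[taxa %in% s]))
  clades <- clades[vapply(clades, length, 1L) > 1L &
                   vapply(clades, length, 1L) < length(taxa)]
  build <- function(members, avail) {
    inside <- avail[vapply(avail, function(s)
      all(s %in% members) && length(s) < length(members), TRUE)]
    maximal <- inside[vapply(seq_along(inside), function(i) {
      !any(vapply(seq_along(inside), function(j)
        j != i && all(inside[[i]] %in% inside[[j]]) &&
          length(inside[[j]]) > length(inside[[i]]), TRUE))
    }, TRUE)]
    covered <- unlist(maximal)
    strs <- c(vapply(maximal, function(s) build(s, inside), ""),
              setdiff(members, covered))
    keys <- c(vapply(maximal, function(s) min(match(s, taxa)), 1),
              match(setdiff(members, covered), taxa))
    paste0("(", paste(strs[order(keys)], collapse = ","), ")")
  }
  nwk <- paste0(build(taxa, clades), ";")
  ape::read.tree(text = nwk)
}

#' The cetacean study taxa
#' @return Character vector of 16 tip labels (15 cetaceans plus hippopotamus
#'   outgroup).
#' @export
cetacean_taxa <- function() {
  c("Tursiops_aduncus", "Tursiops_truncatus", "Delphinus_capensis",
    "Stenella_coeruleoalba", "Stenella_attenuata", "Sousa_chinensis",
    "Grampus_griseus", "Delphinapterus_leucas", "Neophocaena_phocaenoides",
    "Lipotes_vexillifer", "Platanista_gangetica", "Mesoplodon_ginkgodens",
    "Kogia_sima", "Balaenoptera_acutorostrata", "Balaenoptera_omurai",
    "Hippopotamus_amphibius")
}

#' Reference cetacean timetree
#'
#' The 16-taxon dated species tree used as the default simulation condition:
#' flanking-sequence topology with published posterior mean node ages in Ma
#' (crown Cetacea 34.40, crown Odontoceti 29.05, Phocoenidae-Monodontidae
#' 11.39, ...). The root (Cetacea-Hippopotamus split) is set to 52.08 Ma, the
#' median of its fossil calibration.
#'
#' @return A `timetree`.
#' @export
cetacean_timetree <- function() {
  nwk <- paste0(
    "(Hippopotamus_amphibius,((Balaenoptera_acutorostrata,Balaenoptera_omurai),",
    "(Kogia_sima,(Platanista_gangetica,(Mesoplodon_ginkgodens,(Lipotes_vexillifer,",
    "((Neophocaena_phocaenoides,Delphinapterus_leucas),(Grampus_griseus,",
    "((Tursiops_aduncus,Delphinus_capensis),((Sousa_chinensis,Stenella_coeruleoalba),",
    "(Tursiops_truncatus,Stenella_attenuata)))))))))));")
  tree <- ape::read.tree(text = nwk)
  ages <- tibble::tibble(
    taxa = list(
      c("Hippopotamus_amphibius", "Kogia_sima"),
      c("Balaenoptera_acutorostrata", "Kogia_sima"),
      c("Balaenoptera_acutorostrata", "Balaenoptera_omurai"),
      c("Kogia_sima", "Tursiops_aduncus"),
      c("Platanista_gangetica", "Tursiops_aduncus"),
      c("Mesoplodon_ginkgodens", "Tursiops_aduncus"),
      c("Lipotes_vexillifer", "Tursiops_aduncus"),
      c("Neophocaena_phocaenoides", "Tursiops_aduncus"),
      c("Neophocaena_phocaenoides", "Delphinapterus_leucas"),
      c("Grampus_griseus", "Tursiops_aduncus"),
      c("Tursiops_aduncus", "Tursiops_truncatus"),
      c("Tursiops_aduncus", "Delphinus_capensis"),
      c("Sousa_chinensis", "Tursiops_truncatus"),
      c("Sousa_chinensis", "Stenella_coeruleoalba"),
      c("Tursiops_truncatus", "Stenella_attenuata")),
    age_ma = c(52.08, 34.40, 12.09, 29.05, 27.53, 23.88, 19.75,
               15.55, 11.39, 12.90, 9.89, 6.88, 9.18, 7.63, 7.81))
  timetree(tree, age_table = ages)
}

#' Cetacean insertion-marker tree
#'
#' The rooted topology supported by the retroposon presence/absence characters
#' alone: polytomies are retained wherever no insertion marker resolves a
#' split (the two mysticetes; the three delphinoid families beyond the
#' Delphinidae stem; the interior of Delphinidae).
#'
#' @return Rooted `phylo` with polytomies.
#' @export
cetacean_insertion_tree <- function() {
  taxa <- cetacean_taxa()
  delph <- taxa[1:7]
  cet <- setdiff(taxa, "Hippopotamus_amphibius")
  odo <- setdiff(cet, c("Balaenoptera_acutorostrata", "Balaenoptera_omurai"))
  cladeC <- setdiff(odo, "Kogia_sima")
  cladeD <- setdiff(cladeC, "Platanista_gangetica")
  cladeE <- setdiff(cladeD, "Mesoplodon_ginkgodens")
  delphinoidea <- setdiff(cladeE, "Lipotes_vexillifer")
  tree_from_clades(
    list(cet, odo, cladeC, cladeD, cladeE, delphinoidea, delph), taxa)
}

#' Fossil calibration table for the cetacean analysis
#'
#' Four node-age calibrations, each a lognormal prior on age with offset at
#' the younger fossil bound, median at the geometric mean of the bounds, and
#' the stated log-scale SD: Cetacea-Hippopotamidae split 48.6-55.8 Ma (SD
#' 1.2), crown Cetacea 33.5-40 Ma (SD 1.138), crown Odontoceti 23.7-30 Ma (SD
#' 1.119), Phocoenidae-Monodontidae 10-11.2 Ma (SD 1.138).
#'
#' @return Tibble with columns `clade`, `taxa` (list), `lower`, `upper`,
#'   `sdlog`.
#' @export
cetacean_calibrations <- function() {
  tibble::tibble(
    clade = c("root", "crown_cetacea", "crown_odontoceti",
              "phocoenidae_monodontidae"),
    taxa = list(
      c("Hippopotamus_amphibius", "Kogia_sima"),
      c("Balaenoptera_acutorostrata", "Kogia_sima"),
      c("Kogia_sima", "Tursiops_aduncus"),
      c("Neophocaena_phocaenoides", "Delphinapterus_leucas")),
    lower = c(48.6, 33.5, 23.7, 10),
    upper = c(55.8, 40, 30, 11.2),
    sdlog = c(1.2, 1.138, 1.119, 1.138))
}

## lognormal calibration parameters: offset = lower bound, median of the
## lognormal part at geomean(lower, upper) - lower
calibration_params <- function(lower, upper, sdlog) {
  med <- sqrt(lower * upper) - lower
  list(offset = lower, meanlog = log(med), sdlog = sdlog)
}
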