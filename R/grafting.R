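# Taxonomy-guided grafting of study species onto a backbone phylogeny.
#
# Species absent from the backbone are attached next to their nearest
# relative (single congener -> that leaf; several congeners -> their MRCA;
# no congener -> same logic at family rank) with a pendant branch equal to
# the attachment node's own branch length, which creates or enlarges
# polytomies. Polytomies are then resolved by repeatedly grouping two
# randomly chosen children under a new internal node whose branch length is
# half the shortest child branch of the polytomous node, the grouped
# children's branches being shortened by the same amount -- so no leaf's
# distance to the root ever changes.

# ---- internal parent-vector representation -------------------------------
# list(parent = int (0 = root), length = dbl (NA at root), label = chr (NA
# for unnamed internals)). Node ids are positions; appends never renumber.

nodetab_from_phylo <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_all <- n_tip + phy$Nnode
  parent <- integer(n_all)
  len <- rep(NA_real_, n_all)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  len[phy$edge[, 2L]] <- phy$edge.length
  lab <- rep(NA_character_, n_all)
  lab[seq_len(n_tip)] <- phy$tip.label
  if (!is.null(phy$node.label)) {
    keep <- nzchar(phy$node.label)
    lab[n_tip + which(keep)] <- phy$node.label[keep]
  }
  list(parent = parent, length = len, label = lab)
}

nt_children <- function(tab) {
  split(seq_along(tab$parent), factor(tab$parent, levels = 0:length(tab$parent)))
}

nt_is_leaf <- function(tab) {
  !(seq_along(tab$parent) %in% tab$parent)
}

nt_root <- function(tab) which(tab$parent == 0L)

nt_ancestors <- function(tab, id) {
  out <- id
  while (tab$parent[id] != 0L) {
    id <- tab$parent[id]
    out <- c(out, id)
  }
  out
}

# deepest common ancestor; for a single id, the id itself
nt_mrca <- function(tab, ids) {
  ids <- unique(ids)
  common <- nt_ancestors(tab, ids[1L])
  for (j in ids[-1L]) common <- common[common %in% nt_ancestors(tab, j)]
  common[1L]
}

nt_newick <- function(tab, digits = 10) {
  kids <- nt_children(tab)
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  rec <- function(id) {
    ch <- kids[[as.character(id)]]
    lab <- if (!is.na(tab$label[id])) tab$label[id] else ""
    body <- if (length(ch) == 0L) {
      lab
    } else {
      paste0("(", paste(vapply(ch, rec, character(1L)), collapse = ","), ")", lab)
    }
    if (tab$parent[id] == 0L) body else paste0(body, ":", fmt(tab$length[id]))
  }
  paste0(rec(nt_root(tab)), ";")
}

nt_to_phylo <- function(tab) {
  read_newick(nt_newick(tab))
}

# ---- taxonomy helpers ----------------------------------------------------

check_taxonomy <- function(taxonomy) {
  taxonomy <- as_tibble(taxonomy)
  need <- c("species", "genus", "family")
  missing_cols <- setdiff(need, names(taxonomy))
  if (length(missing_cols) > 0L) {
    abort(paste0("taxonomy table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(taxonomy$species)) abort("duplicate species in taxonomy")
  taxonomy
}

# genus/family for each tree leaf: from the taxonomy where recorded,
# otherwise genus from the binomial prefix (Genus_species), family unknown
leaf_taxonomy <- function(labels, taxonomy) {
  idx <- match(labels, taxonomy$species)
  tibble(
    species = labels,
    genus = ifelse(is.na(idx), sub("[_ ].*$", "", labels), taxonomy$genus[idx]),
    family = ifelse(is.na(idx), NA_character_, taxonomy$family[idx])
  )
}

#' Locate the nearest relative of a species in a backbone tree
#'
#' "Nearest relative" is resolved from taxonomy, in the spirit of
#' Phylomatic-style placement: a single congener leaf is the attachment
#' point; several congeners give their MRCA; failing a genus match, the same
#' logic is applied at family rank. Tree leaves absent from the taxonomy
#' table still match at genus rank through their binomial prefix.
#'
#' @param phy Backbone `phylo` tree.
#' @param species Binomial name of the species to place.
#' @param taxonomy Data frame with columns `species`, `genus`, `family`.
#' @return A one-row tibble: `species`, `rank` ("genus" or "family"),
#'   `attachment_node` (ape node id), `attachment_label` (tip label, or a
#'   `mrca(k tips)` description for an internal attachment).
#' @export
find_nearest_relative <- function(phy, species, taxonomy) {
  validate_phylo(phy)
  taxonomy <- check_taxonomy(taxonomy)
  rec <- taxonomy[taxonomy$species == species, ]
  if (nrow(rec) == 0L) {
    abort(paste0("no taxonomy record for species: ", species),
          class = "littertraits_unplaceable")
  }
  leaves <- leaf_taxonomy(phy$tip.label, taxonomy)
  for (rank in c("genus", "family")) {
    key <- rec[[rank]]
    if (is.na(key) || !nzchar(key)) next
    hits <- leaves$species[!is.na(leaves[[rank]]) & leaves[[rank]] == key &
                             leaves$species != species]
    if (length(hits) > 0L) {
      node <- mrca_node(phy, hits)
      lab <- if (length(hits) == 1L) hits else paste0("mrca(", length(hits), " tips)")
      return(tibble(species = species, rank = rank,
                    attachment_node = node, attachment_label = lab))
    }
  }
  abort(paste0("species has no congener or confamilial in the tree: ", species),
        class = "littertraits_unplaceable")
}

# ---- insertion and polytomy resolution (node-table level) ----------------

nt_insert <- function(tab, species, attach_id) {
  par <- tab$parent[attach_id]
  if (par == 0L) {
    abort(paste0("cannot attach '", species, "' above the root"),
          class = "littertraits_root_attachment")
  }
  pend <- tab$length[attach_id]
  new_id <- length(tab$parent) + 1L
  tab$parent[new_id] <- par
  tab$length[new_id] <- pend
  tab$label[new_id] <- species
  list(tab = tab, pendant = pend)
}

nt_depth <- function(tab, id) {
  d <- 0
  while (tab$parent[id] != 0L) {
    d <- d + tab$length[id]
    id <- tab$parent[id]
  }
  d
}

# Multi-relative placement: the new species becomes an extra child of the
# relatives' MRCA, with a pendant branch equal to the relatives' mean depth
# below that node -- on an ultrametric backbone the inserted tip surfaces at
# the same depth as its relatives, so grafting preserves ultrametricity.
nt_insert_child <- function(tab, species, mrca_id, relative_ids) {
  d_m <- nt_depth(tab, mrca_id)
  pend <- max(0, mean(vapply(relative_ids, function(i) nt_depth(tab, i),
                             numeric(1L))) - d_m)
  new_id <- length(tab$parent) + 1L
  tab$parent[new_id] <- mrca_id
  tab$length[new_id] <- pend
  tab$label[new_id] <- species
  list(tab = tab, pendant = pend)
}

# One full resolution of a polytomous node: group random pairs until binary.
# b_new is recomputed from the current child set at every step, so late new
# internal edges can be shorter than early ones.
nt_resolve_node <- function(tab, node) {
  repeat {
    children <- which(tab$parent == node)
    if (length(children) <= 2L) break
    b_new <- 0.5 * min(tab$length[children])
    pick <- children[sample.int(length(children), 2L)]
    z <- length(tab$parent) + 1L
    tab$parent[z] <- node
    tab$length[z] <- b_new
    tab$label[z] <- NA_character_
    tab$parent[pick] <- z
    tab$length[pick] <- tab$length[pick] - b_new
    stopifnot(all(tab$length[pick] >= 0))
  }
  tab
}

#' Insert one species as an extra child next to its attachment node
#'
#' The new leaf is added as an additional child of the attachment node's
#' parent, with a pendant branch length equal to the attachment node's own
#' branch length, so its root-to-tip distance equals that of its nearest
#' relative. No existing edge is modified; the resulting polytomy is left
#' for [resolve_polytomies()].
#'
#' @param phy A `phylo` tree.
#' @param species New leaf label.
#' @param attachment_node ape node id (tip or internal) to attach beside.
#' @return The enlarged `phylo` tree.
#' @export
insert_species <- function(phy, species, attachment_node) {
  validate_phylo(phy)
  if (species %in% phy$tip.label) {
    warn(paste0("species already in tree, skipping: ", species))
    return(phy)
  }
  tab <- nodetab_from_phylo(phy)
  nt_to_phylo(nt_insert(tab, species, attachment_node)$tab)
}

#' Resolve all polytomies, conserving every root-to-tip distance
#'
#' Each polytomous node is resolved by repeatedly drawing two of its current
#' children at random, grouping them under a new internal node whose branch
#' length is half the shortest current child branch, and shortening the two
#' grouped branches by that amount. Leaf depths are exactly conserved;
#' zero-length child branches yield zero-length internal edges.
#'
#' @param phy A `phylo` tree.
#' @param seed Integer seed making the random pair choices reproducible.
#' @return A strictly binary `phylo` tree.
#' @export
resolve_polytomies <- function(phy, seed) {
  validate_phylo(phy)
  withr::with_seed(seed, {
    tab <- nodetab_from_phylo(phy)
    tab <- nt_resolve_all(tab)$tab
    nt_to_phylo(tab)
  })
}

nt_resolve_all <- function(tab) {
  counts <- tabulate(tab$parent, nbins = length(tab$parent))
  poly <- which(counts > 2L)
  for (node in poly) tab <- nt_resolve_node(tab, node)
  list(tab = tab, n_polytomies = length(poly))
}

#' Graft study species onto a backbone tree
#'
#' Runs the full placement procedure: species are processed in alphabetical
#' order; each placeable species is inserted next to its nearest relative
#' (previously inserted species count as potential relatives for later
#' ones). A species with a single relative becomes that leaf's sibling with
#' an equal pendant length; a species with several relatives becomes an
#' extra child of their MRCA with a pendant equal to the relatives' mean
#' depth below that node, so on an ultrametric backbone every inserted tip
#' surfaces at its relatives' depth and the tree stays ultrametric. All
#' polytomies -- pre-existing and newly created -- are then
#' resolved with the distance-conserving rule. The whole run consumes a
#' single seeded random stream, so identical inputs and seed give an
#' identical Newick string.
#'
#' @param phy Backbone `phylo` tree (branch lengths required).
#' @param species Character vector of species to place; those already in the
#'   tree are skipped with a warning recorded in the report.
#' @param taxonomy Data frame with columns `species`, `genus`, `family`.
#' @param seed Integer seed.
#' @return An object of class `graft_result`: a list with `tree` (binary
#'   `phylo`), `report` (tibble: species, status, rank, attachment_label,
#'   pendant_length), `n_polytomies_resolved`, and `seed`.
#' @export
graft_species <- function(phy, species, taxonomy, seed) {
  validate_phylo(phy)
  taxonomy <- check_taxonomy(taxonomy)
  species <- sort(unique(as.character(species)))
  withr::with_seed(seed, {
    tab <- nodetab_from_phylo(phy)
    rows <- vector("list", length(species))
    for (i in seq_along(species)) {
      sp <- species[i]
      leaf_set <- tab$label[nt_is_leaf(tab)]
      if (sp %in% leaf_set) {
        warn(paste0("species already in tree, skipping: ", sp))
        rows[[i]] <- tibble(species = sp, status = "already_present",
                            rank = NA_character_, attachment_label = NA_character_,
                            pendant_length = NA_real_)
        next
      }
      hit <- tryCatch(
        nt_find_attachment(tab, sp, taxonomy),
        littertraits_unplaceable = function(e) NULL
      )
      if (is.null(hit)) {
        rows[[i]] <- tibble(species = sp, status = "unplaceable",
                            rank = NA_character_, attachment_label = NA_character_,
                            pendant_length = NA_real_)
        next
      }
      ins <- tryCatch(
        if (length(hit$relatives) == 1L) {
          nt_insert(tab, sp, hit$node)
        } else {
          nt_insert_child(tab, sp, hit$node, hit$relatives)
        },
        littertraits_root_attachment = function(e) NULL
      )
      if (is.null(ins)) {
        rows[[i]] <- tibble(species = sp, status = "unplaceable",
                            rank = hit$rank, attachment_label = hit$label,
                            pendant_length = NA_real_)
        next
      }
      tab <- ins$tab
      rows[[i]] <- tibble(species = sp, status = "placed", rank = hit$rank,
                          attachment_label = hit$label,
                          pendant_length = ins$pendant)
    }
    res <- nt_resolve_all(tab)
    out <- list(
      tree = nt_to_phylo(res$tab),
      report = dplyr::bind_rows(rows),
      n_polytomies_resolved = res$n_polytomies,
      seed = seed
    )
    class(out) <- "graft_result"
    out
  })
}

# attachment search on the node table (avoids phylo round-trips per species)
nt_find_attachment <- function(tab, species, taxonomy) {
  rec <- taxonomy[taxonomy$species == species, ]
  if (nrow(rec) == 0L) {
    abort(paste0("no taxonomy record for species: ", species),
          class = "littertraits_unplaceable")
  }
  leaf_ids <- which(nt_is_leaf(tab))
  leaves <- leaf_taxonomy(tab$label[leaf_ids], taxonomy)
  for (rank in c("genus", "family")) {
    key <- rec[[rank]]
    if (is.na(key) || !nzchar(key)) next
    sel <- !is.na(leaves[[rank]]) & leaves[[rank]] == key &
      leaves$species != species
    if (any(sel)) {
      ids <- leaf_ids[sel]
      node <- if (length(ids) == 1L) ids else nt_mrca(tab, ids)
      lab <- if (length(ids) == 1L) leaves$species[sel] else
        paste0("mrca(", length(ids), " tips)")
      return(list(node = node, rank = rank, label = lab, relatives = ids))
    }
  }
  abort(paste0("species has no congener or confamilial in the tree: ", species),
        class = "littertraits_unplaceable")
}

#' @method print graft_result
#' @export
print.graft_result <- function(x, ...) {
  placed <- sum(x$report$status == "placed")
  cat("Grafted tree:", length(x$tree$tip.label), "tips;",
      placed, "species placed,",
      sum(x$report$status == "unplaceable"), "unplaceable;",
      x$n_polytomies_resolved, "polytomies resolved (seed", x$seed, ")\n")
  invisible(x)
}

#' @method tidy graft_result
#' @export
tidy.graft_result <- function(x, ...) x$report
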