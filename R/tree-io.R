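#' Read a rooted phylogeny from a Newick string or file
#'
#' Parses Newick (underscore or single-quoted labels, branch lengths on all
#' non-root edges) into an [ape::read.tree()] `phylo` object and validates the
#' invariants the downstream grafting and signal machinery relies on: a single
#' root, unique tip labels, and finite non-negative branch lengths on every
#' edge. Branch lengths are mandatory because the grafting rules are
#' branch-length arithmetic; a tree without them is rejected rather than
#' defaulted.
#'
#' @param x A Newick string (containing `";"`) or the path to a Newick file.
#' @return A validated `phylo` object.
#' @seealso [write_newick()], [root_to_tip_depths()]
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  looks_like_newick <- grepl("[();,]", x)
  if (!looks_like_newick && file.exists(x)) {
    text <- paste(readLines(x, warn = FALSE), collapse = "")
  } else if (looks_like_newick) {
    text <- x
  } else {
    abort(paste0("file not found: ", x))
  }
  check_newick_syntax(text)
  # a bare "Label;" is a single-leaf tree; ape needs the parenthesised form
  if (grepl("^[^();,]+;\\s*$", trimws(text))) {
    text <- paste0("(", sub(";\\s*$", "", trimws(text)), ");")
  }
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e)))
  )
  if (is.null(phy)) abort("Newick parse error: string could not be parsed")
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  validate_phylo(phy)
}

# Cheap structural pre-scan so malformed input fails with a character position
# (the full grammar is ape's job).
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(paste0("Newick parse error at character ", i,
                     ": unmatched ')'"))
      }
    }
  }
  if (in_quote) abort("Newick parse error: unterminated quoted label")
  if (depth != 0L) {
    abort(paste0("Newick parse error at character ", length(chars),
                 ": ", depth, " unclosed '('"))
  }
  if (!grepl(";", text, fixed = TRUE)) {
    abort(paste0("Newick parse error at character ", nchar(text),
                 ": missing terminal ';'"))
  }
  invisible(text)
}

#' Validate the structural invariants of a rooted phylogeny
#'
#' @param phy A `phylo` object.
#' @param allow_polytomies Keep `TRUE` for backbone input; grafted output is
#'   checked binary separately.
#' @return `phy`, invisibly usable, after passing all checks.
#' @export
validate_phylo <- function(phy, allow_polytomies = TRUE) {
  if (!inherits(phy, "phylo")) abort("not a 'phylo' object")
  n_tip <- length(phy$tip.label)
  if (n_tip >= 1L && anyDuplicated(phy$tip.label)) {
    dups <- unique(phy$tip.label[duplicated(phy$tip.label)])
    abort(paste0("duplicate leaf label(s): ", paste(dups, collapse = ", ")))
  }
  if (n_tip > 1L) {
    if (is.null(phy$edge.length)) {
      abort("branch lengths are required on all non-root edges")
    }
    if (anyNA(phy$edge.length) || any(!is.finite(phy$edge.length))) {
      abort("branch lengths must be finite (missing lengths are not defaulted)")
    }
    if (any(phy$edge.length < 0)) abort("negative branch length")
    # exactly one root: one node never appears as a child
    child <- phy$edge[, 2L]
    parent <- phy$edge[, 1L]
    roots <- setdiff(unique(parent), child)
    if (length(roots) != 1L) abort("tree must have exactly one root")
    if (!allow_polytomies && !ape::is.binary(phy)) {
      abort("tree contains unresolved polytomies")
    }
  }
  phy
}

#' Write a phylogeny as Newick
#'
#' Branch lengths are emitted with 10 significant digits so that write/parse
#' round-trips preserve lengths to well under 1e-9 relative error.
#'
#' @param phy A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly when written to `file`).
#' @export
write_newick <- function(phy, file = NULL, digits = 10) {
  validate_phylo(phy)
  s <- if (length(phy$tip.label) == 1L) {
    paste0(phy$tip.label, ";")
  } else {
    ape::write.tree(phy, digits = digits)
  }
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Root-to-tip path lengths
#'
#' @param phy A `phylo` object.
#' @return A tibble with columns `label` and `depth` (sum of branch lengths on
#'   the root-to-tip path), one row per tip, in tip-label order of the tree.
#' @export
#' @examples
#' root_to_tip_depths(read_newick("((A:1,B:2):1,C:4);"))
root_to_tip_depths <- function(phy) {
  validate_phylo(phy)
  if (length(phy$tip.label) == 1L) {
    return(tibble(label = phy$tip.label, depth = 0))
  }
  d <- ape::node.depth.edgelength(phy)
  tibble(label = phy$tip.label, depth = d[seq_along(phy$tip.label)])
}

#' Is a tree ultrametric?
#'
#' Uses a relative criterion: the tree is ultrametric when
#' `max(depth) - min(depth) <= tol * max(depth)`. Time-calibrated trees should
#' pass at tight tolerances; the pipeline reports but never requires it.
#'
#' @param phy A `phylo` object.
#' @param tol Relative tolerance.
#' @return Logical scalar.
#' @export
is_ultrametric <- function(phy, tol = 1e-8) {
  d <- root_to_tip_depths(phy)$depth
  if (length(d) < 2L) return(TRUE)
  mx <- max(d)
  if (mx == 0) return(TRUE)
  (mx - min(d)) <= tol * mx
}

#' Most recent common ancestor of a set of tips
#'
#' @param phy A `phylo` object.
#' @param labels Character vector of tip labels (one or more).
#' @return The ape node id of the MRCA; for a single label, the tip itself.
#' @export
mrca_node <- function(phy, labels) {
  validate_phylo(phy)
  unknown <- setdiff(labels, phy$tip.label)
  if (length(unknown) > 0L) {
    abort(paste0("unknown tip label(s): ", paste(unknown, collapse = ", ")))
  }
  if (length(labels) == 0L) abort("at least one label required")
  if (length(unique(labels)) == 1L) {
    return(match(labels[1L], phy$tip.label))
  }
  ape::getMRCA(phy, unique(labels))
}
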