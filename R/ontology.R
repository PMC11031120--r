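# Disease ontology: a single-rooted DAG of diagnostic codes (ICD-10-like)
# with ancestor lookup, used by the GRAM-style disease encoder.

#' Construct a disease ontology from child -> parent edges
#'
#' @param parent_edges Two-column data.frame or matrix (child, parent).
#' @return Object of class \code{trial_ontology}: list with \code{codes},
#'   \code{parents} (list: code -> character vector of parents), and
#'   \code{root}.
#' @export
ontology <- function(parent_edges) {
  pe <- as.data.frame(parent_edges, stringsAsFactors = FALSE)
  stopifnot(ncol(pe) >= 2)
  child <- as.character(pe[[1]]); parent <- as.character(pe[[2]])
  if (any(child == parent)) {
    bad <- child[child == parent][1]
    stop("cycle in ontology: self-edge at code '", bad, "'")
  }
  codes <- sort(unique(c(child, parent)))
  roots <- setdiff(codes, unique(child))
  if (length(roots) == 0L)
    stop("cycle in ontology: every code has a parent (offending edge: ",
         child[1], " -> ", parent[1], ")")
  if (length(roots) > 1L)
    stop("ontology must have a single root; found: ",
         paste(roots, collapse = ", "))
  parents <- split(parent, child)
  # Kahn toposort from the root downward doubles as the cycle check:
  # in-degree of a code = number of parent edges into it
  indeg <- stats::setNames(integer(length(codes)), codes)
  cnt <- table(child)
  indeg[names(cnt)] <- as.integer(cnt)
  children <- split(child, parent)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    q <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[q]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(codes))
    stop("cycle in ontology involving: ",
         paste(utils::head(names(indeg)[indeg > 0L], 5), collapse = ", "))
  structure(list(codes = codes, parents = parents, root = roots),
            class = "trial_ontology")
}

#' Ancestors of a code (the code itself first, then all ancestors up to root)
#'
#' @param onto A \code{trial_ontology}.
#' @param code A single code present in the ontology.
#' @return Character vector: the code, then every distinct ancestor.
#' @export
ancestors <- function(onto, code) {
  stopifnot(inherits(onto, "trial_ontology"))
  if (!code %in% onto$codes) stop("unknown ontology code: '", code, "'")
  out <- code
  frontier <- code
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(onto$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Leaf codes (no children) of an ontology
#' @param onto A \code{trial_ontology}.
#' @return Character vector of leaves.
#' @export
ontology_leaves <- function(onto) {
  withkids <- unique(unlist(onto$parents, use.names = FALSE))
  setdiff(onto$codes, withkids)
}

#' @export
print.trial_ontology <- function(x, ...) {
  cat(sprintf("Disease ontology: %d codes, root '%s', %d leaves\n",
              length(x$codes), x$root, length(ontology_leaves(x))))
  invisible(x)
}

#' Generate a balanced synthetic disease ontology
#'
#' A balanced tree of diagnostic-style codes with a single root; with
#' branching b > 1 and depth h it has (b^(h+1) - 1)/(b - 1) codes.
#' Deterministic for a given seed.
#'
#' @param depth Tree depth (root = depth 0). Must be >= 0.
#' @param branching Children per internal node. Must be >= 1.
#' @param seed Integer seed.
#' @return A \code{trial_ontology}.
#' @examples
#' gen_ontology(depth = 1, branching = 3)  # root + 3 leaves
#' @export
gen_ontology <- function(depth = 3, branching = 3, seed = 1) {
  if (depth < 0 || branching < 1) stop("need depth >= 0 and branching >= 1")
  set.seed(seed)
  root <- "ROOT"
  if (depth == 0)
    return(structure(list(codes = root, parents = list(), root = root),
                     class = "trial_ontology"))
  child <- character(0); parent <- character(0)
  level <- root
  for (h in seq_len(depth)) {
    nxt <- character(0)
    for (p in level) {
      kids <- if (p == "ROOT") sprintf("C%02d", seq_len(branching))
              else paste0(p, ".", seq_len(branching))
      child <- c(child, kids); parent <- c(parent, rep(p, branching))
      nxt <- c(nxt, kids)
    }
    level <- nxt
  }
  ontology(data.frame(child = child, parent = parent))
}
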