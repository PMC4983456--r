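#' @title Convolution subset-tree kernel
#' @description
#' The kernel counts the subset-tree fragments two parse trees share, each
#' fragment decayed by `lambda^(number of productions)` so large fragments
#' do not dominate.  It is computed with the usual `Delta` recursion over
#' node pairs: 0 when the productions differ, `lambda` for matching
#' pre-terminals, and `lambda * prod_k (1 + Delta(child_k, child_k))`
#' otherwise.  Node pairs are evaluated once each (bottom-up over a
#' post-order flattening), so the cost is O(|N1| * |N2|).
#' @name tree_kernel
NULL

# flatten a parse tree into post-order arrays: production strings, child ids
# (labeled children only; lexical leaves fold into the production), and a
# pre-terminal flag.  The root is the last entry.
pn_flatten <- function(tree) {
  prods <- character(0)
  kids <- list()
  pre <- logical(0)
  rec <- function(node) {
    kid_ids <- integer(0)
    parts <- character(0)
    for (ch in node$children) {
      if (pn_is_leaf(ch)) {
        parts <- c(parts, ch$word)
      } else {
        kid_ids <- c(kid_ids, rec(ch))
        parts <- c(parts, ch$label)
      }
    }
    prods[[length(prods) + 1L]] <<- paste(
      node$label, "->", paste(parts, collapse = " ")
    )
    kids[[length(kids) + 1L]] <<- kid_ids
    pre[[length(pre) + 1L]] <<- pn_is_preterminal(node)
    length(prods)
  }
  if (pn_is_leaf(tree)) {
    stop("cannot flatten a bare leaf")
  }
  rec(tree)
  list(prods = prods, kids = kids, pre = pre)
}

ctk_delta_matrix <- function(f1, f2, lambda) {
  n1 <- length(f1$prods)
  n2 <- length(f2$prods)
  D <- matrix(0, n1, n2)
  idx2 <- split(seq_len(n2), f2$prods)
  for (i in seq_len(n1)) {
    js <- idx2[[f1$prods[i]]]
    if (is.null(js)) next
    if (f1$pre[i]) {
      D[i, js] <- lambda
    } else {
      k1 <- f1$kids[[i]]
      for (j in js) {
        if (length(k1)) {
          D[i, j] <- lambda * prod(1 + D[cbind(k1, f2$kids[[j]])])
        } else {
          D[i, j] <- lambda
        }
      }
    }
  }
  D
}

#' Delta: shared rooted fragments of two nodes
#'
#' Evaluates the kernel recursion at a single node pair: the decayed count
#' of subset-tree fragments rooted at both nodes.
#'
#' @param n1,n2 `parse_node` objects (subtree roots).
#' @param lambda Decay factor in (0, 1).
#' @return Nonnegative numeric value.
#' @examples
#' tree_delta(pn("NN", "protein"), pn("NN", "protein"), lambda = 0.4)
#' @export
tree_delta <- function(n1, n2, lambda = 0.4) {
  f1 <- pn_flatten(n1)
  f2 <- pn_flatten(n2)
  D <- ctk_delta_matrix(f1, f2, lambda)
  D[length(f1$prods), length(f2$prods)]
}

#' Convolution tree kernel between two trees
#'
#' Sums `Delta` over all node pairs; with `normalize = TRUE` the value is
#' divided by `sqrt(ctk(t1, t1) * ctk(t2, t2))`, giving unit
#' self-similarity.
#'
#' @param t1,t2 `parse_node` objects.
#' @param lambda Decay factor in (0, 1).
#' @param normalize Normalize to unit self-similarity (default `FALSE` for
#'   the raw kernel value).
#' @return Numeric kernel value.
#' @export
ctk <- function(t1, t2, lambda = 0.4, normalize = FALSE) {
  f1 <- pn_flatten(t1)
  f2 <- pn_flatten(t2)
  k <- sum(ctk_delta_matrix(f1, f2, lambda))
  if (normalize) {
    s1 <- sum(ctk_delta_matrix(f1, f1, lambda))
    s2 <- sum(ctk_delta_matrix(f2, f2, lambda))
    if (s1 <= 0 || s2 <= 0) {
      return(0)
    }
    k <- k / sqrt(s1 * s2)
  }
  k
}

#' Gram matrix of a tree set
#'
#' Pairwise kernel values for a list of trees, computed once per unique
#' serialized tree and expanded, which makes template-derived corpora cheap.
#' The result is symmetric and positive semidefinite; with normalization the
#' diagonal is exactly 1.
#'
#' @param trees List of `parse_node` objects.
#' @param lambda Decay factor in (0, 1).
#' @param normalize Normalize to unit self-similarity (default `TRUE`).
#' @param ids Optional candidate ids for the dimnames.
#' @return A numeric matrix of class `gram_matrix`.
#' @export
gram_matrix <- function(trees, lambda = 0.4, normalize = TRUE, ids = NULL) {
  stopifnot(length(trees) >= 1L)
  keys <- vapply(trees, write_bracketed_tree, character(1))
  ukeys <- unique(keys)
  uidx <- match(keys, ukeys)
  flats <- lapply(trees[match(ukeys, keys)], pn_flatten)
  m <- length(ukeys)
  K <- matrix(0, m, m)
  for (a in seq_len(m)) {
    for (b in a:m) {
      K[a, b] <- sum(ctk_delta_matrix(flats[[a]], flats[[b]], lambda))
      K[b, a] <- K[a, b]
    }
  }
  if (normalize) {
    d <- sqrt(diag(K))
    d[d == 0] <- 1
    K <- K / tcrossprod(d)
  }
  out <- K[uidx, uidx, drop = FALSE]
  if (is.null(ids)) ids <- as.character(seq_along(trees))
  dimnames(out) <- list(ids, ids)
  class(out) <- c("gram_matrix", class(out))
  out
}

#' Cross kernel matrix between two tree sets
#'
#' Kernel values with `trees1` in rows and `trees2` in columns, deduplicated
#' the same way as [gram_matrix()]; normalization divides by the self
#' kernels of both trees.
#'
#' @param trees1,trees2 Lists of `parse_node` objects.
#' @param lambda Decay factor in (0, 1).
#' @param normalize Normalize to unit self-similarity (default `TRUE`).
#' @return A numeric matrix, `length(trees1)` by `length(trees2)`.
#' @export
gram_cross <- function(trees1, trees2, lambda = 0.4, normalize = TRUE) {
  k1 <- vapply(trees1, write_bracketed_tree, character(1))
  k2 <- vapply(trees2, write_bracketed_tree, character(1))
  u1 <- unique(k1)
  u2 <- unique(k2)
  f1 <- lapply(trees1[match(u1, k1)], pn_flatten)
  f2 <- lapply(trees2[match(u2, k2)], pn_flatten)
  K <- matrix(0, length(u1), length(u2))
  for (a in seq_along(u1)) {
    for (b in seq_along(u2)) {
      K[a, b] <- sum(ctk_delta_matrix(f1[[a]], f2[[b]], lambda))
    }
  }
  if (normalize) {
    s1 <- sqrt(vapply(f1, function(f) sum(ctk_delta_matrix(f, f, lambda)),
                      numeric(1)))
    s2 <- sqrt(vapply(f2, function(f) sum(ctk_delta_matrix(f, f, lambda)),
                      numeric(1)))
    s1[s1 == 0] <- 1
    s2[s2 == 0] <- 1
    K <- K / outer(s1, s2)
  }
  K[match(k1, u1), match(k2, u2), drop = FALSE]
}

#' Enumerate the subset-tree fragments of a tree
#'
#' Brute-force realization of the kernel's feature map: every fragment
#' obtained by expanding each node with either none or all of its children
#' (grammar-preserving), rooted at every labeled node.  Used as the
#' independent oracle for the recursive kernel; guarded to small trees
#' because the fragment count grows exponentially.
#'
#' @param tree A `parse_node` with at most `max_nodes` labeled nodes.
#' @param max_nodes Combinatorial guard (default 12).
#' @return Tibble with one row per fragment occurrence: `fragment` (string
#'   form) and `n_productions` (its decay exponent).
#' @export
enumerate_subset_trees <- function(tree, max_nodes = 12L) {
  if (tree_size(tree) > max_nodes) {
    stop("tree too large for fragment enumeration (", tree_size(tree),
         " > ", max_nodes, " nodes)")
  }
  rooted <- function(node) {
    # fragments rooted at `node` with the root expanded
    opts_per_child <- lapply(node$children, function(ch) {
      if (pn_is_leaf(ch)) {
        list(list(repr = ch$word, np = 0L))
      } else {
        c(list(list(repr = ch$label, np = 0L)), rooted(ch))
      }
    })
    combos <- list(list(reprs = character(0), np = 0L))
    for (opts in opts_per_child) {
      combos <- unlist(lapply(combos, function(cm) {
        lapply(opts, function(o) {
          list(reprs = c(cm$reprs, o$repr), np = cm$np + o$np)
        })
      }), recursive = FALSE)
    }
    lapply(combos, function(cm) {
      list(
        repr = paste0("(", node$label, " ",
                      paste(cm$reprs, collapse = " "), ")"),
        np = cm$np + 1L
      )
    })
  }
  all_frags <- unlist(
    lapply(pn_nodes(tree), rooted),
    recursive = FALSE
  )
  tibble::tibble(
    fragment = vapply(all_frags, `[[`, character(1), "repr"),
    n_productions = vapply(all_frags, `[[`, integer(1), "np")
  )
}

#' Decay-weighted inner product of fragment enumerations
#'
#' Oracle counterpart of [ctk()]: `sum_i c1(i) * c2(i) * lambda^p(i)` over
#' shared fragment types, where `p(i)` is the fragment's production count.
#'
#' @param t1,t2 Small `parse_node` objects.
#' @param lambda Decay factor.
#' @return Numeric kernel value; equals `ctk(t1, t2, lambda)`.
#' @export
subset_tree_inner_product <- function(t1, t2, lambda = 0.4) {
  f1 <- enumerate_subset_trees(t1)
  f2 <- enumerate_subset_trees(t2)
  c1 <- dplyr::count(f1, .data$fragment, .data$n_productions)
  c2 <- dplyr::count(f2, .data$fragment, .data$n_productions)
  shared <- dplyr::inner_join(c1, c2, by = c("fragment", "n_productions"))
  sum(shared$n.x * shared$n.y * lambda^shared$n_productions)
}
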