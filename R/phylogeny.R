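## IUPAC-aware p-distances, a deterministic neighbor-joining implementation,
## site-resampling bootstrap (via ape::boot.phylo) and clade queries.
## Trees are ape "phylo" objects throughout; Newick IO goes through ape.

## lazily built 15x15 per-site mismatch lookup between IUPAC codes
.iupac_mismatch_env <- new.env(parent = emptyenv())

.iupac_mismatch <- function() {
  if (!is.null(.iupac_mismatch_env$m)) return(.iupac_mismatch_env$m)
  codes <- names(.IUPAC_SETS)
  m <- matrix(0, length(codes), length(codes),
              dimnames = list(codes, codes))
  for (a in codes) {
    for (b in codes) {
      A <- .IUPAC_SETS[[a]]
      B <- .IUPAC_SETS[[b]]
      m[a, b] <- 1 - length(intersect(A, B)) / max(length(A), length(B))
    }
  }
  .iupac_mismatch_env$m <- m
  m
}

#' IUPAC-aware pairwise p-distance
#'
#' Mean per-site mismatch where each IUPAC code expands to its base set and
#' the mismatch between sets A and B is `1 - |A n B| / max(|A|, |B|)`: two
#' plain bases score 0 or 1, a plain base against its two-base superset
#' scores 0.5, identical codes score 0.  With `model = "jc69"` the
#' Jukes-Cantor correction `-(3/4) log(1 - 4p/3)` is applied; at the tiny
#' divergences involved here the correction is immaterial.
#'
#' @param seq_a,seq_b Equal-length sequence strings.
#' @param model `"p"` (default) or `"jc69"`.
#' @return Distance (fraction).
#' @examples
#' pairwise_distance("ACGT", "ACGA")  # 0.25
#' pairwise_distance("AC", "AY")      # 0.25 (C vs Y scores 0.5)
#' @export
pairwise_distance <- function(seq_a, seq_b, model = c("p", "jc69")) {
  model <- match.arg(model)
  a <- .seq_chars(seq_a)
  b <- .seq_chars(seq_b)
  if (length(a) != length(b)) {
    stop("sequences differ in length", call. = FALSE)
  }
  m <- .iupac_mismatch()
  p <- mean(m[cbind(a, b)])
  if (model == "jc69") {
    if (p >= 0.75) stop("p-distance too large for JC69", call. = FALSE)
    p <- -0.75 * log(1 - 4 * p / 3)
  }
  p
}

#' Pairwise distance matrix over a set of sequences
#'
#' @param seqs Named character vector of equal-length sequences.
#' @param model Passed to [pairwise_distance()].
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(seqs, model = "p") {
  labs <- names(seqs)
  if (is.null(labs) || anyDuplicated(labs)) {
    stop("sequences must carry unique names", call. = FALSE)
  }
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- pairwise_distance(seqs[[i]], seqs[[j]], model)
    }
  }
  d
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param dm Matrix from [distance_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(dm, path) {
  labs <- rownames(dm)
  lines <- c(sprintf("%5d", nrow(dm)),
             vapply(seq_len(nrow(dm)), function(i) {
               paste0(formatC(labs[i], width = -10L),
                      paste(sprintf("%.8f", dm[i, ]), collapse = "  "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Neighbor-joining tree with deterministic tie-breaking
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i, j) = (r - 2) d(i, j) - R(i) - R(j)` is joined; ties are broken by
#' the lowest pair in the current label order, so the same matrix always
#' yields the same tree.  Negative branch-length estimates are clamped to
#' zero with a message.
#'
#' @param dm Symmetric distance matrix with unique dimnames (>= 3 taxa).
#' @return An unrooted `phylo` object (ape).
#' @examples
#' seqs <- c(a = "AAAA", b = "AAAT", c = "TTAA", d = "TTAT")
#' nj_tree(distance_matrix(seqs))
#' @export
nj_tree <- function(dm) {
  if (!all(is.finite(dm))) stop("non-finite distances", call. = FALSE)
  labs <- rownames(dm)
  n <- length(labs)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  D <- unname(as.matrix(dm))
  frag <- labs  # newick fragment per active node
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) clamped <<- TRUE
    max(x, 0)
  }
  fmt <- function(x) sprintf("%.12g", x)

  while (length(frag) > 3L) {
    r <- length(frag)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    ## lowest pair first: scan the upper triangle in row-major order
    best <- c(NA_integer_, NA_integer_)
    qmin <- Inf
    for (i in seq_len(r - 1L)) {
      for (j in (i + 1L):r) {
        if (Q[i, j] < qmin) {
          qmin <- Q[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1L]
    j <- best[2L]
    vi <- clamp(D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2)))
    vj <- clamp(D[i, j] - (D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))))
    newfrag <- paste0("(", frag[i], ":", fmt(vi), ",",
                      frag[j], ":", fmt(vj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    D <- D2
  }

  a <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  c3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- paste0("(", frag[1L], ":", fmt(a), ",", frag[2L], ":", fmt(b),
                ",", frag[3L], ":", fmt(c3), ");")
  if (clamped) message("negative NJ branch length estimate clamped to 0")
  ape::read.tree(text = nwk)
}

#' Site-resampling bootstrap supports for the NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and reports for every internal edge of the original tree
#' the percentage of replicates containing the same bipartition
#' (ape::boot.phylo does the counting).
#'
#' @param seqs Named character vector of equal-length sequences.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Optional seed for the resampling.
#' @param model Distance model passed through.
#' @return The NJ `phylo` with `node.label` set to integer percent support
#'   (the root label is empty).
#' @export
bootstrap_support <- function(seqs, replicates = 1000L, seed = NULL,
                              model = "p") {
  if (replicates < 1L) stop("need at least 1 replicate", call. = FALSE)
  x <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
  rownames(x) <- names(seqs)
  tree <- nj_tree(distance_matrix(seqs, model))
  rebuild <- function(mat) {
    s <- apply(mat, 1L, paste, collapse = "")
    suppressMessages(nj_tree(distance_matrix(s, model)))
  }
  counts <- .with_seed(seed, {
    ape::boot.phylo(tree, x, rebuild, B = replicates, quiet = TRUE,
                    rooted = FALSE)
  })
  support <- round(100 * counts / replicates)
  support[1L] <- NA  # root "bipartition" is trivial
  tree$node.label <- ifelse(is.na(support), "", as.character(support))
  tree
}

#' Split a tree at the edge best separating a set of reference leaves
#'
#' Considers every internal edge as a bipartition of the leaves and prefers
#' edges that cleanly separate the reference labels (one side contains all
#' of them, the other none); among clean edges the one with the longest
#' branch is taken, since branch length measures how strongly the data
#' support the separation.  If no edge is clean, the bipartition with the
#' smallest symmetric difference to the reference set is used and a message
#' is emitted.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param reference_labels Non-empty proper subset of the tip labels.
#' @return List: `inside` (tips on the reference side), `outside`,
#'   `edge_length`, `clean` (logical).
#' @examples
#' seqs <- c(a = "AAAAA", b = "AAAAT", c = "TTTTA", d = "TTTTT")
#' clade_partition(nj_tree(distance_matrix(seqs)), "c")$inside
#' @export
clade_partition <- function(tree, reference_labels) {
  tips <- tree$tip.label
  if (length(reference_labels) == 0L ||
      !all(reference_labels %in% tips) ||
      length(reference_labels) >= length(tips)) {
    stop("reference_labels must be a non-empty proper subset of the tips",
         call. = FALSE)
  }
  R <- reference_labels
  ntip <- length(tips)
  pp <- ape::prop.part(tree)
  best <- NULL
  for (nd in seq_along(pp)[-1L]) {  # node 1 is the root: trivial split
    side_a <- tips[pp[[nd]]]
    side_b <- setdiff(tips, side_a)
    edge <- which(tree$edge[, 2L] == ntip + nd)
    len <- if (length(edge)) tree$edge.length[edge] else 0
    for (inside in list(side_a, side_b)) {
      outside <- setdiff(tips, inside)
      clean <- all(R %in% inside) && !any(R %in% outside)
      symdiff <- length(setdiff(inside, R)) + length(setdiff(R, inside))
      cand <- list(inside = inside, outside = outside, edge_length = len,
                   clean = clean, symdiff = symdiff)
      if (is.null(best) ||
          (cand$clean && !best$clean) ||
          (cand$clean && best$clean &&
             (len > best$edge_length ||
                (len == best$edge_length &&
                   length(inside) < length(best$inside)))) ||
          (!cand$clean && !best$clean && symdiff < best$symdiff)) {
        best <- cand
      }
    }
  }
  if (!best$clean) {
    message("no single internal edge cleanly separates the reference ",
            "labels; returning the maximal-agreement bipartition")
  }
  best$symdiff <- NULL
  best
}
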