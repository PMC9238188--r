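# GO enrichment of extreme rank changes: nearest-rank 2.5% tails of the
# per-feature rank-change distribution, tested per term with a one-sided
# Fisher's exact test under the elim decorrelation algorithm (genes of a
# significant child term are removed from its ancestors before those are
# tested).

#' Select the extreme tails of a per-feature statistic
#'
#' Nearest-rank quantiles: the low set is every feature at or below the
#' q-quantile value, the high set every feature at or above the
#' (1-q)-quantile value. Ties spanning a cutpoint are all included, so a
#' set can exceed q*n features.
#'
#' @param x named numeric vector (per-feature rank change).
#' @param q tail fraction (default 0.025, the 2.5% extremes).
#' @return list: `low`, `high` (character vectors of names), `cut_low`,
#'   `cut_high`.
#' @export
select_extremes <- function(x, q = 0.025) {
  n <- length(x)
  if (n < 1 / q) stop("need at least 1/q features")
  if (is.null(names(x))) stop("x must be named")
  xs <- sort(x)
  cut_low <- xs[nearest_rank(n, q)]
  cut_high <- xs[n - nearest_rank(n, q) + 1L]
  list(low = names(x)[x <= cut_low], high = names(x)[x >= cut_high],
       cut_low = cut_low, cut_high = cut_high)
}

#' Build a GO-like DAG object
#'
#' @param terms data.frame(term_id, name, namespace).
#' @param edges data.frame(child, parent) of is_a relations (must be
#'   acyclic; every non-root term needs a path to a root).
#' @return object of class `go_dag` with per-term depth (longest path to a
#'   root) and parent/child indices.
#' @export
go_dag <- function(terms, edges) {
  ids <- terms$term_id
  stopifnot(!anyDuplicated(ids), all(edges$child %in% ids),
            all(edges$parent %in% ids))
  parents <- split(edges$parent, factor(edges$child, levels = ids))
  children <- split(edges$child, factor(edges$parent, levels = ids))
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  roots <- ids[lengths(parents) == 0]
  if (!length(roots)) stop("DAG has no root")
  depth[roots] <- 0L
  # longest path to a root; repeated relaxation doubles as a cycle check
  for (iter in seq_len(length(ids) + 1)) {
    changed <- FALSE
    for (id in ids) {
      ps <- parents[[id]]
      if (length(ps) && !anyNA(depth[ps])) {
        d <- max(depth[ps]) + 1L
        if (is.na(depth[id]) || d > depth[id]) {
          depth[id] <- d; changed <- TRUE
        }
      }
    }
    if (!changed) break
    if (iter == length(ids) + 1) stop("cycle detected in DAG")
  }
  if (anyNA(depth)) stop("some terms have no path to a root")
  structure(list(terms = terms, parents = parents, children = children,
                 depth = depth), class = "go_dag")
}

# all ancestors of a term (excluding itself)
go_ancestors <- function(dag, id) {
  seen <- character(0); queue <- dag$parents[[id]]
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]
    if (!(a %in% seen)) {
      seen <- c(seen, a)
      queue <- c(queue, dag$parents[[a]])
    }
  }
  seen
}

#' Propagate gene annotations up the DAG (true-path rule)
#'
#' @param dag a `go_dag`.
#' @param ann data.frame(gene, term_id) of direct annotations.
#' @return named list term_id -> character vector of genes (closed under
#'   is_a).
#' @export
propagate_annotation <- function(dag, ann) {
  ids <- dag$terms$term_id
  direct <- split(ann$gene, factor(ann$term_id, levels = ids))
  prop <- lapply(direct, unique)
  names(prop) <- ids
  # children before parents: descending depth
  for (id in ids[order(dag$depth[ids], decreasing = TRUE)]) {
    for (p in dag$parents[[id]])
      prop[[p]] <- unique(c(prop[[p]], prop[[id]]))
  }
  prop
}

#' GO enrichment by Fisher's exact test with the elim algorithm
#'
#' Terms are processed children before parents (decreasing depth, ties in
#' lexical order for determinism). Each term is tested one-sided
#' (enrichment) on the 2x2 table of study/background against its current --
#' possibly pruned -- gene set; when a term is significant at `alpha`, its
#' current genes are removed from all its ancestors' gene sets before those
#' are tested. `p_classic` is the same test without any elimination.
#'
#' @param study_genes,background_genes study set (must be contained in the
#'   background) and gene universe.
#' @param dag a `go_dag`.
#' @param ann direct annotation data.frame(gene, term_id).
#' @param alpha elimination threshold (default 0.05).
#' @return data.frame(term_id, name, p_elim, p_classic, n_study, n_term,
#'   significant), ordered by p_elim.
#' @export
elim_fisher <- function(study_genes, background_genes, dag, ann,
                        alpha = 0.05) {
  study_genes <- unique(study_genes)
  background_genes <- unique(background_genes)
  if (!length(study_genes)) stop("empty study set")
  missing <- setdiff(study_genes, background_genes)
  if (length(missing))
    stop("study gene absent from background: ", missing[1])
  prop <- propagate_annotation(dag, ann)
  prop <- lapply(prop, intersect, background_genes)
  N <- length(background_genes)
  n_study <- length(study_genes)
  fisher_tail <- function(k, K) {
    # one-sided enrichment: P(X >= k), X ~ Hypergeom(N, K, n_study)
    stats::phyper(k - 1, K, N - K, n_study, lower.tail = FALSE)
  }
  ids <- dag$terms$term_id
  ord <- ids[order(-dag$depth[ids], ids)]
  current <- prop
  res <- data.frame(term_id = ids,
                    name = dag$terms$name[match(ids, dag$terms$term_id)],
                    p_elim = NA_real_, p_classic = NA_real_,
                    n_study = NA_integer_, n_term = NA_integer_,
                    stringsAsFactors = FALSE)
  for (id in ord) {
    genes_now <- current[[id]]
    k <- length(intersect(genes_now, study_genes))
    K <- length(genes_now)
    p <- fisher_tail(k, K)
    k0 <- length(intersect(prop[[id]], study_genes))
    i <- match(id, res$term_id)
    res$p_elim[i] <- p
    res$p_classic[i] <- fisher_tail(k0, length(prop[[id]]))
    res$n_study[i] <- k
    res$n_term[i] <- K
    if (p < alpha) {
      for (a in go_ancestors(dag, id))
        current[[a]] <- setdiff(current[[a]], genes_now)
    }
  }
  res$significant <- res$p_elim < alpha
  res[order(res$p_elim, res$term_id), ]
}

#' Simulate a GO-like DAG with propagated annotations
#'
#' Random layered DAG plus direct gene annotations, for testing enrichment
#' machinery at desk scale (synthetic stand-in for a curated ontology).
#'
#' @param n_terms terms beside the root.
#' @param n_genes genes in the universe.
#' @param terms_per_gene mean direct annotations per gene.
#' @param max_parents maximum is_a parents per term.
#' @param seed integer seed.
#' @return list: `dag` (a `go_dag`), `ann` (gene, term_id), `genes`.
#' @export
simulate_go <- function(n_terms = 100, n_genes = 500, terms_per_gene = 2,
                        max_parents = 2, seed = 1) {
  with_seed(substream_seed(seed, "go"), {
    ids <- c("GO:ROOT", sprintf("GO:%06d", seq_len(n_terms)))
    edges <- list()
    for (i in seq_len(n_terms)) {
      np <- sample.int(max_parents, 1)
      pool <- ids[seq_len(i)]   # earlier terms only: acyclic by construction
      ps <- unique(sample(pool, min(np, length(pool))))
      edges[[i]] <- data.frame(child = ids[i + 1], parent = ps,
                               stringsAsFactors = FALSE)
    }
    genes <- sprintf("g%04d", seq_len(n_genes))
    nn <- pmin(pmax(1, stats::rpois(n_genes, terms_per_gene)), n_terms)
    ann <- data.frame(
      gene = rep(genes, nn),
      term_id = unlist(lapply(nn, function(k) sample(ids[-1], k))),
      stringsAsFactors = FALSE)
    list(dag = go_dag(data.frame(term_id = ids,
                                 name = paste("term", ids),
                                 namespace = "BP",
                                 stringsAsFactors = FALSE),
                      do.call(rbind, edges)),
         ann = ann, genes = genes)
  })
}
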