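test_that("extreme selection uses nearest-rank quantiles and keeps ties", {
  x <- setNames(seq_len(200), paste0("f", 1:200))
  ext <- select_extremes(x, q = 0.025)
  expect_length(ext$low, 5)
  expect_length(ext$high, 5)
  expect_setequal(ext$low, paste0("f", 1:5))
  expect_setequal(ext$high, paste0("f", 196:200))
  # symmetric distribution -> equal tail sizes
  y <- setNames(c(-(50:1), 50:1), paste0("g", 1:100))
  e2 <- select_extremes(y, 0.05)
  expect_equal(length(e2$low), length(e2$high))
  # ties across the cutpoint are all included (checked against sort-slice)
  z <- setNames(c(rep(1, 10), 2:91), paste0("h", 1:100))
  e3 <- select_extremes(z, 0.025)
  zs <- sort(z)
  cut <- zs[ceiling(100 * 0.025)]
  expect_setequal(e3$low, names(z)[z <= cut])
  expect_gte(length(e3$low), ceiling(100 * 0.025))
  expect_error(select_extremes(setNames(1:10, letters[1:10]), 0.025), "1/q")
})

test_that("flat-DAG elim p-values equal the factorial hypergeometric oracle", {
  dag <- flat_dag(4)
  genes <- sprintf("g%03d", 1:60)
  set.seed(5)
  ann <- data.frame(gene = genes,
                    term_id = sample(sprintf("GO:L%02d", 1:4), 60,
                                     replace = TRUE),
                    stringsAsFactors = FALSE)
  study <- sample(genes, 12)
  res <- elim_fisher(study, genes, dag, ann, alpha = 1e-12)  # no elimination
  for (i in which(res$term_id != "GO:ROOT")) {
    term_genes <- ann$gene[ann$term_id == res$term_id[i]]
    k <- length(intersect(term_genes, study))
    p0 <- fisher_tail_oracle(k, length(term_genes), 60, 12)
    expect_equal(res$p_elim[i], p0, tolerance = 1e-10)
    expect_equal(res$p_classic[i], p0, tolerance = 1e-10)
  }
})

test_that("a parent annotated only through a significant child is eliminated", {
  ids <- c("root", "parent", "child")
  dag <- go_dag(data.frame(term_id = ids, name = ids, namespace = "BP",
                           stringsAsFactors = FALSE),
                data.frame(child = c("parent", "child"),
                           parent = c("root", "parent"),
                           stringsAsFactors = FALSE))
  genes <- sprintf("g%02d", 1:40)
  ann <- data.frame(gene = genes[1:8], term_id = "child",
                    stringsAsFactors = FALSE)
  study <- genes[1:8]            # exactly the child's genes: very enriched
  res <- elim_fisher(study, genes, dag, ann, alpha = 0.05)
  expect_lt(res$p_elim[res$term_id == "child"], 0.05)
  expect_equal(res$p_elim[res$term_id == "parent"], 1)
  expect_lt(res$p_classic[res$term_id == "parent"], 0.05)
})

test_that("degenerate and invalid study sets behave as specified", {
  dag <- flat_dag(3)
  genes <- sprintf("g%02d", 1:30)
  set.seed(2)
  ann <- data.frame(gene = genes,
                    term_id = sample(sprintf("GO:L%02d", 1:3), 30,
                                     replace = TRUE),
                    stringsAsFactors = FALSE)
  res <- elim_fisher(genes, genes, dag, ann)   # study = background
  expect_true(all(res$p_elim == 1))
  expect_error(elim_fisher(character(0), genes, dag, ann), "empty")
  expect_error(elim_fisher(c(genes[1], "gXX"), genes, dag, ann), "gXX")
})

test_that("elim never finds more significant terms than classic", {
  for (s in 1:5) {
    go <- simulate_go(n_terms = 40, n_genes = 150, seed = s)
    set.seed(s)
    study <- sample(go$genes, 20)
    res <- elim_fisher(study, go$genes, go$dag, go$ann, alpha = 0.05)
    expect_lte(sum(res$p_elim < 0.05), sum(res$p_classic < 0.05))
  }
})

test_that("gene input order never changes the enrichment table", {
  go <- simulate_go(n_terms = 30, n_genes = 100, seed = 9)
  set.seed(9)
  study <- sample(go$genes, 15)
  r1 <- elim_fisher(study, go$genes, go$dag, go$ann)
  r2 <- elim_fisher(rev(study), rev(go$genes), go$dag,
                    go$ann[rev(seq_len(nrow(go$ann))), ])
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("annotation propagation is closed under is_a", {
  go <- simulate_go(n_terms = 25, n_genes = 80, seed = 4)
  prop <- propagate_annotation(go$dag, go$ann)
  for (id in go$dag$terms$term_id) {
    for (p in go$dag$parents[[id]]) {
      expect_true(all(prop[[id]] %in% prop[[p]]))
    }
  }
})
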