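# Library screening and diversity clustering.

# One fixed model shared by the screening tests.
screening_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      smiles <- c("NS(=O)(=O)c1ccccc1", "CNS(=O)(=O)c1ccccc1",
                  "NS(=O)(=O)C1CCCCC1", "NS(=O)(=O)c1ccncc1",
                  "CCOc1ccccc1", "CCCCc1ccccc1", "CCN(CC)c1ccccc1",
                  "Cc1ccc(C)cc1")
      X <- fingerprint_matrix(standardize_structure(smiles), "morgan")
      y <- rep(c("ACTIVE", "INACTIVE"), each = 4)
      cache <<- vs_train(X, y, "knn",
                         list(n_neighbors = 3L, weights = "distance"))
    }
    cache
  }
})

test_that("screening standardizes, scores and ranks a library", {
  lib <- c("NS(=O)(=O)c1ccc(C)cc1",   # sulfonamide: should score high
           "CCCCCc1ccccc1",           # plain alkylbenzene: low
           "CCOc1ccc(C)cc1.Cl")       # salt form: must standardize first
  hits <- screen_library(screening_model(), lib, retention = "ps_at_least",
                         threshold = 0)
  expect_s3_class(hits, "vs_hits")
  expect_equal(nrow(hits), 3)
  expect_identical(hits$rank, 1:3)
  expect_true(all(diff(hits$ps) <= 0))
  expect_equal(hits$canonical_smiles[1],
               standardize_structure("NS(=O)(=O)c1ccc(C)cc1"))
})

test_that("max-PS retention keeps exactly the argmax set", {
  lib <- c("NS(=O)(=O)c1ccccc1",      # in the training set: ps = 1
           "CNS(=O)(=O)c1ccccc1",     # also a training active: ps = 1
           "CCOc1ccccc1",             # training inactive
           "CCCCc1ccccc1")
  hits <- screen_library(screening_model(), lib, retention = "max_ps")
  ps_all <- predict(screening_model(),
                    fingerprint_matrix(standardize_structure(lib), "morgan"))
  expect_equal(sort(hits$ps), sort(ps_all[ps_all >= max(ps_all) - 1e-9]))
  expect_true(all(hits$ps >= max(ps_all) - 1e-9))
  # every omitted compound scores strictly below the maximum
  omitted <- setdiff(standardize_structure(lib), hits$canonical_smiles)
  expect_true(all(ps_all[match(omitted, standardize_structure(lib))] <
                    max(ps_all) - 1e-9))
})

test_that("screening scores are invariant to library input order", {
  lib <- c("NS(=O)(=O)c1ccc(C)cc1", "CCCCCc1ccccc1", "CCOc1ccc(C)cc1",
           "NS(=O)(=O)c1ccc(F)cc1")
  h1 <- screen_library(screening_model(), lib, retention = "ps_at_least",
                       threshold = 0)
  h2 <- screen_library(screening_model(), rev(lib), retention = "ps_at_least",
                       threshold = 0)
  m <- match(h1$canonical_smiles, h2$canonical_smiles)
  expect_equal(h1$ps, h2$ps[m])
})

test_that("invalid libraries are rejected, partly-invalid ones trimmed", {
  expect_error(screen_library(screening_model(), c("C1CC", "[Na+].[Cl-]")),
               "no valid molecules")
  expect_warning(
    hits <- screen_library(screening_model(), c("CCOc1ccccc1", "C1CC"),
                           retention = "ps_at_least", threshold = 0),
    "dropped")
  expect_equal(nrow(hits), 1)
})

test_that("diversity clustering groups identical and separates unrelated hits", {
  mk_hits <- function(smiles, ps = seq(0.9, by = -0.05,
                                       length.out = length(smiles))) {
    structure(data.frame(canonical_smiles = standardize_structure(smiles),
                         ps = ps, rank = seq_along(smiles),
                         stringsAsFactors = FALSE),
              summary = list(), class = c("vs_hits", "data.frame"))
  }
  # identical structures collapse to one cluster
  twice <- diversity_filter(mk_hits(c("CCO", "CCO")), 0.9)
  expect_equal(twice$cluster_id, c(1L, 1L))
  expect_length(attr(twice, "representatives"), 1)
  # benzene and ethanol share no Morgan environments
  far <- diversity_filter(mk_hits(c("c1ccccc1", "CCO")), 0.9)
  expect_equal(far$cluster_id, c(1L, 2L))
  # cutoff 0 merges everything into the first leader's cluster
  all_in <- diversity_filter(mk_hits(c("c1ccccc1", "CCO", "CCN", "CCCC")), 0)
  expect_equal(unique(all_in$cluster_id), 1L)
  expect_error(diversity_filter(mk_hits("CCO"), 1.5), "similarity_cutoff")
})

test_that("representative count never grows as the cutoff drops", {
  smiles <- c("NS(=O)(=O)c1ccccc1", "CNS(=O)(=O)c1ccccc1", "CCO", "CCCO",
              "c1ccccc1", "Cc1ccccc1")
  hits <- structure(data.frame(canonical_smiles = standardize_structure(smiles),
                               ps = seq(0.9, by = -0.05, length.out = 6),
                               rank = 1:6, stringsAsFactors = FALSE),
                    summary = list(), class = c("vs_hits", "data.frame"))
  n_rep <- vapply(c(0.9, 0.6, 0.3, 0), function(cut) {
    length(attr(diversity_filter(hits, cut), "representatives"))
  }, 0L)
  expect_true(all(diff(n_rep) <= 0))
})
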