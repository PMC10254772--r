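# Generative-chemistry metrics: exact small cases, independent oracles,
# and the bounded-fraction / identity invariants.

test_that("validity and Unique@k on hand-built lists match exact fractions", {
  expect_equal(validity_fraction(c("CCO", "c1ccccc1")), 1.0)
  expect_equal(validity_fraction(c("C(", "CCO")), 0.5)
  expect_error(validity_fraction(character(0)), "empty")

  # OCC duplicates CCO canonically
  expect_equal(unique_at_k(c("CCO", "OCC", "CCN", "CCC"), 4), 0.75)
  expect_equal(unique_at_k(rep("CCO", 10), 10), 0.1)
  expect_equal(unique_at_k(c("CCO", "OCC", "CCN", "CCC"), 2), 0.5)
  expect_error(unique_at_k(c("CCO"), 5), "k=5")
})

test_that("novelty counts distinct canonical forms absent from training", {
  expect_equal(novelty(c("CCO", "OCC"), c("CCO", "CCN")), 0.0)
  expect_equal(novelty(c("CCF", "CCCl"), c("CCO", "CCN")), 1.0)
  expect_equal(novelty(c("CCO", "CCF"), c("OCC")), 0.5)
  expect_error(novelty(character(0), "CCO"), "non-empty")
  # complement identity: novelty + fraction-in-training == 1
  gen <- c("CCO", "CCN", "CCCC", "c1ccccc1")
  train <- c("OCC", "c1ccccc1C")
  canon_gen <- unique(canonicalize_smiles(gen))
  canon_train <- canonicalize_smiles(train)
  expect_equal(novelty(gen, train) + mean(canon_gen %in% canon_train), 1.0)
})

test_that("fragment similarity: identity, disjoint supports, hand vectors", {
  set_a <- c("CCOc1ccccc1N", "CCNC(=O)c1ccccc1")
  expect_equal(fragment_similarity(set_a, set_a), 1.0)

  # unbreakable alkanes contribute only themselves as "fragments":
  # disjoint support from set_a, hence orthogonal count vectors
  expect_equal(fragment_similarity(set_a, c("CCCC", "CCC")), 0)

  # explicit fragment-count-vector oracle, counts assembled by hand from
  # per-molecule BRICS calls
  ns <- asNamespace("condsmiles")
  set_b <- c("CCOc1ccccc1N", "CCCNC(=O)CC")
  frag_of <- function(smi) {
    unlist(ns$chem_call("brics",
                        list(smiles = as.list(canonicalize_smiles(smi))))$fragments)
  }
  counts <- function(smis) {
    all_frags <- unlist(lapply(smis, frag_of))
    table(all_frags)
  }
  ca <- counts(set_a)
  cb <- counts(set_b)
  keys <- union(names(ca), names(cb))
  va <- ifelse(is.na(ca[keys]), 0, ca[keys])
  vb <- ifelse(is.na(cb[keys]), 0, cb[keys])
  want <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  expect_equal(fragment_similarity(set_a, set_b), want, tolerance = 1e-12)
  expect_gt(want, 0)
  expect_lt(want, 1)
})

test_that("SNN: self-identity and brute-force Tanimoto oracle on one pair", {
  set_a <- c("CCOc1ccccc1", "CCN", "c1ccncc1")
  expect_equal(snn(set_a, set_a), 1.0)

  # independent bitset oracle for a single generated/reference pair
  ns <- asNamespace("condsmiles")
  pair <- c("CCO", "CCN")
  bits <- ns$chem_call("morgan", list(smiles = as.list(pair), radius = 2L,
                                      n_bits = 1024L, use_features = FALSE))$bits
  a <- unlist(bits[[1]])
  b <- unlist(bits[[2]])
  tanimoto <- length(intersect(a, b)) / length(union(a, b))
  expect_equal(snn(pair[1], pair[2]), tanimoto, tolerance = 1e-12)
  expect_gt(tanimoto, 0)
  expect_lt(tanimoto, 1)
})

test_that("Wasserstein-1: identities, shift, brute-force matching oracle", {
  expect_equal(wasserstein1(c(1, 2, 3), c(1, 2, 3)), 0.0)
  expect_equal(wasserstein1(c(1, 2, 3), c(2, 3, 4)), 1.0)
  # equal-size samples: optimal transport = sorted pairing; check against
  # exhaustive assignment enumeration at n=6
  set.seed(8)
  a <- round(rnorm(6), 3)
  b <- round(rnorm(6, mean = 0.4), 3)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- min(vapply(perms(b), function(p) mean(abs(a - p)), numeric(1)))
  expect_equal(wasserstein1(a, b), best, tolerance = 1e-12)
  expect_error(wasserstein1(numeric(0), 1), "non-empty")
})

test_that("W1 is symmetric and satisfies the triangle inequality", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(sample(3:12, 1))
    y <- rnorm(sample(3:12, 1), mean = 1)
    z <- rexp(sample(3:12, 1))
    expect_equal(wasserstein1(x, y), wasserstein1(y, x), tolerance = 1e-12)
    expect_lte(wasserstein1(x, z),
               wasserstein1(x, y) + wasserstein1(y, z) + 1e-12)
  }
})

test_that("property profile: descriptor values and in-range percentages", {
  # ethanol: one donor (OH), one acceptor (O)
  prof <- property_profile("CCO")
  tab <- prof$table
  expect_equal(tab$hbd, 1)
  expect_equal(tab$hba, 1)
  expect_true(tab$hbd <= 5 && tab$hba <= 10)
  expect_equal(unname(prof$in_range["hbd"]), 100)
  expect_equal(unname(prof$in_range["mw"]), 0)  # MW(ethanol) < 200

  # a mid-sized molecule sits inside the MW window
  prof2 <- property_profile("CC(=O)Nc1ccc(O)cc1OCCN")  # MW ~ 224
  expect_equal(unname(prof2$in_range["mw"]), 100)
  expect_error(property_profile("C("), "invalid")
})

test_that("evaluate_generation: degenerate and identity configurations", {
  all_bad <- evaluate_generation(c("C(", ")("), ref_test = c("CCO"))
  expect_equal(all_bad$valid, 0)
  expect_true(is.na(all_bad$frag_test))
  expect_match(all_bad$flags, "no valid")

  same <- c("CCOc1ccccc1N", "CCNC(=O)c1ccccc1", "c1ccc2ccccc2c1")
  rep <- evaluate_generation(same, ref_test = same, training_set = same,
                             k_unique = 3L)
  expect_equal(rep$valid, 1.0)
  expect_equal(rep$novelty, 0.0)
  expect_equal(rep$frag_test, 1.0)
  expect_equal(rep$snn_test, 1.0)
  expect_equal(unname(rep$w1_by_property), rep(0, 4))
  expect_equal(unname(rep$unique_at_k["unique_at_3"]), 1.0)

  # all fractions bounded
  expect_true(all(vapply(
    c(rep$valid, rep$novelty, rep$frag_test, rep$snn_test),
    function(v) v >= 0 && v <= 1, logical(1))))

  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$valid, 1.0)
})
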