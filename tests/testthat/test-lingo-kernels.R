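smi1 <- "OC(O)=O"
smi2_zeroed <- "CCCCC(O)=C0"

test_that("LINGO extraction reproduces the worked q=4 profiles", {
  p1 <- extract_lingos(smi1)
  expect_identical(p1[c("OC(O", "C(O)", "(O)=", "O)=O")],
                   c(`OC(O` = 1L, `C(O)` = 1L, `(O)=` = 1L, `O)=O` = 1L))
  expect_length(p1, 4)
  p2 <- extract_lingos(smi2_zeroed)
  expect_identical(p2[["CCCC"]], 2L)
  expect_length(p2, 7)                    # CCCC + six singletons
  expect_identical(sum(p2), 8L)           # n - (q - 1) with multiplicity
  expect_length(extract_lingos("AB"), 0)  # shorter than q
})

test_that("LINGO count with multiplicity is n - (q - 1) for random strings", {
  set.seed(5)
  for (i in 1:20) {
    q <- sample(3:5, 1)
    s <- random_string(sample(q:25, 1))
    expect_identical(sum(extract_lingos(s, q = q)),
                     nchar(s) - (q - 1L), info = s)
  }
})

test_that("LINGOsim matches the worked 2/9 and its degenerate cases", {
  p1 <- extract_lingos(smi1); p2 <- extract_lingos(smi2_zeroed)
  expect_equal(lingosim(p1, p2), 2 / 9)
  expect_equal(lingosim(p1, p1), 1)
  expect_equal(lingosim(extract_lingos("AAAAA"), extract_lingos("NNNNN")), 0)
  expect_warning(v <- lingosim(extract_lingos("A"), extract_lingos("B")),
                 "empty")
  expect_equal(v, 0)
  expect_error(lingosim(extract_lingos(smi1, q = 3), p2), "mismatch")
})

test_that("sublinear TF weighting has the right branch structure", {
  expect_equal(tf_weight(c(0, 1, 2)), c(0, 1, 1 + log10(2)))
  expect_error(tf_weight(-1))
})

test_that("vocabulary construction counts documents, not occurrences", {
  profs <- list(
    structure(c(A = 2L), q = 1L),
    structure(c(A = 1L, B = 1L), q = 1L)
  )
  v <- build_vocabulary(profs)
  expect_identical(v$terms, c("A", "B"))
  expect_identical(unname(v$doc_freq), c(2L, 1L))
  expect_identical(v$n_docs, 2L)
  # the worked pair spans nine unique LINGOs
  v9 <- build_vocabulary(list(extract_lingos(smi1),
                              extract_lingos(smi2_zeroed)))
  expect_length(v9$terms, 9)
  # single-profile corpus: every doc_freq is 1
  v1 <- build_vocabulary(list(extract_lingos(smi2_zeroed)))
  expect_true(all(v1$doc_freq == 1L))
  expect_error(build_vocabulary(list()), "empty")
})

test_that("IDF is log10(N/df) with no smoothing", {
  v <- structure(list(terms = c("(=O)", "O)CO", "ALL"),
                      doc_freq = c(`(=O)` = 300L, `O)CO` = 18L, ALL = 445L),
                      n_docs = 445L, q = 4L),
                 class = "lingo_vocabulary")
  expect_equal(round(idf("(=O)", v), 2), 0.17, ignore_attr = TRUE)
  expect_equal(round(idf("O)CO", v), 2), 1.39, ignore_attr = TRUE)
  expect_equal(idf("ALL", v), 0, ignore_attr = TRUE)
  expect_error(idf("none", v), "not in vocabulary")
})

test_that("vectorize reproduces the worked TF vectors in corpus order", {
  p1 <- extract_lingos(smi1); p2 <- extract_lingos(smi2_zeroed)
  vocab <- build_vocabulary(list(p1, p2))
  v1 <- vectorize(p1, vocab, "tf")
  v2 <- vectorize(p2, vocab, "tf")
  expect_equal(as.numeric(v1), c(1, 1, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(as.numeric(v2), c(0, 1, 1, 0, 1 + log10(2), 1, 1, 1, 1))
  # empty profile -> all-zero vector; out-of-vocabulary terms are dropped
  expect_equal(as.numeric(vectorize(extract_lingos("AB"), vocab, "tf")),
               numeric(9))
  foreign <- extract_lingos("NNNNNN")
  vf <- vectorize(foreign, vocab, "tf")
  expect_equal(as.numeric(vf), numeric(9))
  expect_identical(attr(vf, "n_dropped"), length(foreign))
  # tf-idf with every doc_freq = n_docs weights everything to zero
  flat <- build_vocabulary(list(p1, p1))
  expect_equal(as.numeric(vectorize(p1, flat, "tf-idf")), numeric(4))
})

test_that("TF cosine similarity of the worked pair is 2/5.54", {
  p1 <- extract_lingos(smi1); p2 <- extract_lingos(smi2_zeroed)
  vocab <- build_vocabulary(list(p1, p2))
  v1 <- vectorize(p1, vocab, "tf"); v2 <- vectorize(p2, vocab, "tf")
  cs <- cosine_similarity(v1, v2)
  expect_equal(cs, 2 / (2 * sqrt(6 + (1 + log10(2))^2)))
  expect_equal(round(cs, 2), 0.36)
  expect_equal(cosine_similarity(v2, v2), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_warning(z <- cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
  expect_equal(z, 0)
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)), "length mismatch")
})

test_that("cosine of the printed rounded TF-IDF vectors is 0.61/8.2", {
  # the published arithmetic uses vectors already rounded to 1-2 decimals;
  # reproducing it exactly therefore starts from those printed weights
  v1 <- c(2.3, 0.5, 0.6, 0.4, 0, 0, 0, 0, 0)
  v2 <- c(0, 0.5, 0.6, 0, 1.04, 0.9, 1, 2, 1.9)
  expect_equal(sum(v1 * v2), 0.61)
  expect_equal(round(cosine_similarity(v1, v2), 2), 0.07)
  # full-precision TF-IDF from the printed per-LINGO document frequencies
  # gives the same pair a slightly larger value (~0.084)
  df <- c(2, 113, 105, 143, 61, 49, 36, 4, 5)
  idfs <- log10(445 / df)
  t1 <- c(1, 1, 1, 1, 0, 0, 0, 0, 0)
  t2 <- c(0, 1, 1, 0, 1 + log10(2), 1, 1, 1, 1)
  full <- cosine_similarity(t1 * idfs, t2 * idfs)
  expect_equal(round(full, 2), 0.08)
})

test_that("lingosim and cosine stay in [0,1] and symmetric on random pairs", {
  set.seed(17)
  profs <- lapply(1:12, function(i) extract_lingos(random_string(sample(6:20, 1))))
  vocab <- build_vocabulary(profs)
  for (i in 1:15) {
    a <- sample(profs, 1)[[1]]; b <- sample(profs, 1)[[1]]
    ls <- lingosim(a, b)
    expect_equal(ls, lingosim(b, a))
    expect_gte(ls, 0); expect_lte(ls, 1)
    va <- vectorize(a, vocab, "tf-idf"); vb <- vectorize(b, vocab, "tf-idf")
    cs <- suppressWarnings(cosine_similarity(va, vb))
    expect_equal(cs, suppressWarnings(cosine_similarity(vb, va)))
    expect_gte(cs, 0); expect_lte(cs, 1 + 1e-12)
  }
})

test_that("lingo_report ranks stop-word-like LINGOs first", {
  corp <- prepare_compounds(data.frame(
    id = c("a", "b", "c"),
    smiles = c("CCCCN", "CCCCO", "CCCCS")))
  rep <- lingo_report(corp, q = 4, top_k = 10)
  expect_identical(rep$lingo[1], "CCCC")     # present in all three
  expect_identical(rep$doc_freq[1], 3L)
  expect_equal(rep$idf[1], 0)
  expect_true(all(diff(rep$idf) >= 0))
  expect_error(lingo_report(corp, top_k = 0), "positive")
  # a planted ubiquitous motif dominates a random corpus
  set.seed(23)
  corp2 <- generate_smiles_corpus(synthetic_spec(n_drugs = 30, n_clusters = 1,
                                                 motif_len = 6, seed = 23))
  motif <- attr(corp2, "motifs")[1]
  full <- lingo_report(corp2, q = 4, top_k = 10000)
  expect_identical(full$doc_freq[1], 30L)
  motif_grams <- substring(motif, 1:3, 4:6)
  expect_true(all(full$doc_freq[match(motif_grams, full$lingo)] == 30L))
})
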