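## Hand-checkable corpora: g1 = {"AAA"}, g2 = {"CCC"} at K = 2 give
## Pr(AA) = (1 + 0.5)/(2 + 1) = 0.5, q_{g1,AA} = 1.5/2 = 0.75 and
## q_{g2,AA} = 0.5/2 = 0.25.

test_that("log priors follow genus abundances or stay flat", {
  p <- computeLogPriors(c(g1 = 1, g2 = 3), "abundance")
  expect_equal(unname(p), c(log2(0.25), log2(0.75)))
  expect_equal(sum(2^p), 1)
  ## equal sizes: abundance priors are constant, like flat
  pe <- computeLogPriors(c(a = 5, b = 5), "abundance")
  expect_equal(unname(pe), rep(-1, 2))
  expect_equal(unname(computeLogPriors(c(a = 2, b = 9, c = 1), "flat")),
               rep(0, 3))
  expect_error(computeLogPriors(integer(0)), "empty")
})

test_that("RDP training reproduces the pseudo-probability formulas", {
  m <- trainRdp(c(a = "AAA", b = "CCC"), c("g1", "g2"), 2)
  expect_equal(unname(m@wordPrior["AA"]), 0.5)              # (1+.5)/3
  ## a word absent everywhere: Pr = 0.5/3; genus of size 1 without it:
  ## q = (0 + 0.5/3)/2
  expect_equal(unname(m@wordPrior["AG"]), 0.5 / 3)
  expect_equal(unname(2^m@logQ["g1", "AG"]), (0.5 / 3) / 2)
  expect_equal(unname(2^m@logQ["g1", "AA"]), 0.75)
  expect_equal(unname(2^m@logQ["g2", "AA"]), 0.25)
  expect_true(all(m@logQ < 0))                              # q in (0,1)
  expect_error(trainRdp(c("AAA", "CCC"), c("g1", NA), 2), "unlabelled")
})

test_that("RDP scoring is p + L a' and flat priors can be omitted", {
  m <- trainRdp(c(a = "AAA", b = "CCC"), c("g1", "g2"), 2)
  z <- scoreGenera(m, c(q = "AAA"))
  expect_equal(unname(z[1, ]), c(log2(0.75), log2(0.25)))
  cl <- classifySequences(m, c(q = "AAA"))
  expect_equal(cl$assigned, "g1")
  ## flat-prior scores differ from prior-omitted ones by a shared constant
  ## only, so assignments coincide; abundance priors with equal sizes too
  za <- scoreGenera(m, c(q = "AAA"), prior = "abundance")
  expect_equal(assignFromScores(za, m@genera)$assigned,
               assignFromScores(z, m@genera)$assigned)
  ## zero-evidence query: identical scores for all genera -> unclassified
  cl0 <- suppressWarnings(classifySequences(m, c(q = "NNN")))
  expect_equal(cl0$assigned, "unclassified")
  cl0a <- suppressWarnings(classifySequences(m, c(q = "NNN"),
                                             prior = "abundance"))
  expect_equal(cl0a$assigned, "unclassified")
})

test_that("RDP log-score argmax equals the raw-product posterior argmax", {
  ## independent oracle on D = 16 instances: recompute all probabilities
  ## from scratch with loops and raw products of Eqs for the posterior
  set.seed(202)
  for (rep in 1:8) {
    corp <- randomCorpus(maxGenera = 4, maxPerGenus = 4,
                         minLen = 10, maxLen = 40)
    m <- trainRdp(corp$seqs, corp$genus, 2)
    words <- oracleWordList(2)
    pres <- t(vapply(corp$seqs,
                     function(s) as.numeric(oracleCountKmers(s, 2) > 0),
                     numeric(16)))
    N <- nrow(pres)
    prW <- (colSums(pres) + 0.5) / (N + 1)
    genera <- sort(unique(corp$genus))
    for (qrep in 1:5) {
      qseq <- randomSeq(sample(8:40, 1))
      a <- as.numeric(oracleCountKmers(qseq, 2) > 0)
      post <- vapply(genera, function(g) {
        rows <- pres[corp$genus == g, , drop = FALSE]
        q <- (colSums(rows) + prW) / (nrow(rows) + 1)
        prod(ifelse(a == 1, q, 1))          # Pr(a|g), flat prior
      }, numeric(1))
      oracleBest <- names(post)[which.max(post)]
      got <- classifySequences(m, setNames(qseq, "q"))$assigned
      ## oracle has no tie handling; only compare clear winners
      if (sum(abs(post - max(post)) < 1e-15 * max(post)) == 1L)
        expect_equal(got, oracleBest)
    }
  }
})

test_that("multinomial training matches the pseudo-count formulas", {
  m <- trainMultinomial(c(a = "AAA"), "g1", 2)
  expect_equal(unname(2^m@logQ[1, "AA"]), 0.6875)     # 2.0625 / 3
  expect_equal(unname(2^m@logQ[1, "AC"]), 0.0625 / 3)
  expect_equal(sum(2^m@logQ[1, ]), 1)
  expect_true(all(2^m@logQ > 0))                      # pseudo-counts
  ## two genera with identical K-mer totals get identical rows
  m2 <- trainMultinomial(c(a = "AACC", b = "AACC"), c("g1", "g2"), 2)
  expect_equal(unname(m2@logQ[1, ]), unname(m2@logQ[2, ]))
})

test_that("multinomial scoring is p + L a' and matches the exact likelihood", {
  m <- trainMultinomial(c(a = "AAA", b = "CCC"), c("g1", "g2"), 2)
  z <- scoreGenera(m, c(q = "AAAA"))
  expect_equal(unname(z[1, 1]), 3 * m@logQ["g1", "AA"])
  ## zero query scores equal the priors alone
  z0 <- suppressWarnings(scoreGenera(m, c(q = "NN"), prior = "abundance"))
  expect_equal(unname(z0[1, ]),
               unname(computeLogPriors(setNames(m@genusSizes, m@genera),
                                       "abundance")))
  ## oracle: adding the multinomial coefficient (constant per query) and
  ## ranking exact log-likelihoods gives the same argmax
  set.seed(203)
  for (rep in 1:8) {
    corp <- randomCorpus(maxGenera = 4, maxPerGenus = 4,
                         minLen = 15, maxLen = 60)
    mm <- trainMultinomial(corp$seqs, corp$genus, 2)
    q <- 2^mm@logQ
    for (qrep in 1:4) {
      qseq <- randomSeq(sample(10:50, 1))
      a <- oracleCountKmers(qseq, 2)
      ll <- vapply(seq_len(nrow(q)), function(g)
        lgamma(sum(a) + 1) - sum(lgamma(a + 1)) + sum(a * log(q[g, ])),
        numeric(1))
      got <- classifySequences(mm, setNames(qseq, "q"))$assigned
      if (sum(max(ll) - ll < 1e-12) == 1L)
        expect_equal(got, mm@genera[which.max(ll)])
    }
  }
})

test_that("Markov transitions normalize per pretext and score additively", {
  m <- trainMarkov(c(a = "AAA"), "g1", 2)
  ## pretext A: F(AA) = 2.0625, others 0.0625, block sum 2.25
  expect_equal(unname(2^m@logQ[1, "AA"]), 2.0625 / 2.25)
  expect_equal(unname(2^m@logQ[1, "AC"]), 0.0625 / 2.25)
  ## unseen pretext C: uniform 1/4
  expect_equal(unname(2^m@logQ[1, c("CA", "CC", "CG", "CT")]), rep(0.25, 4))
  ## every (genus, pretext) quadruple sums to 1
  qs <- tapply(2^m@logQ[1, ], pretextGroups(kmerDictionary(2)), sum)
  expect_equal(as.vector(qs), rep(1, 4))
  ## scores: query AAAA has AA = 3
  expect_equal(unname(scoreGenera(m, c(q = "AAAA"))[1, 1]),
               3 * log2(2.0625 / 2.25))
  expect_equal(unname(scoreGenera(m, c(q = "CCCC"))[1, 1]),
               3 * log2(0.25))
  expect_error(trainMarkov(c(a = "AAA"), "g1", 1), "K >= 2")
})

test_that("nearest neighbour matches a brute-force distance scan", {
  tr <- c(a = "AAA", b = "CCC")
  m <- trainNn(tr, c("g1", "g2"), 2)
  ## identity: query equal to a training sequence, distance 0
  cl <- classifySequences(m, c(q = "AAA"))
  expect_equal(cl$assigned, "g1")
  expect_equal(cl$score, 0)
  ## exact equidistance between two genera -> unclassified
  m2 <- trainNn(c(a = "AAAA", b = "CCCC"), c("g1", "g2"), 2)
  ## "AACC" counts AA, AC, CC once each: symmetric to both references
  clt <- classifySequences(m2, c(q = "AACC"))
  expect_equal(clt$assigned, "unclassified")
  ## brute-force all-pairs oracle on random instances
  set.seed(204)
  for (rep in 1:6) {
    corp <- randomCorpus(maxGenera = 5, maxPerGenus = 5,
                         minLen = 20, maxLen = 80)
    mm <- trainNn(corp$seqs, corp$genus, 3)
    profs <- t(vapply(corp$seqs, function(s) {
      v <- oracleCountKmers(s, 3); v / sum(v)
    }, numeric(64)))
    for (qrep in 1:4) {
      qseq <- randomSeq(sample(20:80, 1))
      qv <- oracleCountKmers(qseq, 3); qv <- qv / sum(qv)
      d <- apply(profs, 1, function(r) sqrt(sum((qv - r)^2)))
      best <- which(d - min(d) <= 1e-12 * max(1, min(d)))
      oracle <- if (length(unique(corp$genus[best])) == 1L)
        corp$genus[best[1]] else "unclassified"
      expect_equal(classifySequences(mm, setNames(qseq, "q"))$assigned,
                   oracle)
    }
  }
})

test_that("argmax assignment declares ties unclassified and shifts freely", {
  r <- assignFromScores(rbind(c(-1, -2, -3)), genera = c("a", "b", "c"))
  expect_equal(r$assigned, "a")
  expect_equal(r$margin, 1)
  r2 <- assignFromScores(rbind(c(-1, -1, -3)), genera = c("a", "b", "c"))
  expect_equal(r2$assigned, "unclassified")
  ## shift invariance
  set.seed(1)
  z <- matrix(rnorm(30), 10, 3)
  expect_equal(assignFromScores(z + 7, letters[1:3])$assigned,
               assignFromScores(z, letters[1:3])$assigned)
  expect_error(assignFromScores(matrix(numeric(0), 1, 0)), "empty")
  expect_error(assignFromScores(rbind(c(1, NA))), "finite")
})

test_that("training is invariant to the order of training records", {
  set.seed(205)
  corp <- randomCorpus(maxGenera = 4, maxPerGenus = 5)
  qs <- setNames(replicate(5, randomSeq(50)), paste0("q", 1:5))
  perm <- sample(length(corp$seqs))
  for (method in c("rdp", "multinomial", "markov", "nn")) {
    m1 <- trainClassifier(corp$seqs, corp$genus, 3, method = method)
    m2 <- trainClassifier(corp$seqs[perm], corp$genus[perm], 3,
                          method = method)
    expect_equal(classifySequences(m1, qs)$assigned,
                 classifySequences(m2, qs)$assigned,
                 info = method)
  }
})

test_that("disjoint-alphabet genera are perfectly separated at K = 2", {
  set.seed(206)
  corp <- disjointCorpus(nPer = 4, L = 60)
  for (method in c("rdp", "multinomial", "markov", "nn")) {
    m <- trainClassifier(corp$seqs, corp$genus, 2, method = method)
    got <- classifySequences(m, corp$seqs)$assigned
    expect_equal(got, corp$genus, info = method)
  }
})

test_that("degenerate training sequences are skipped by NN with a warning", {
  seqs <- c(a = "AAAA", b = "NNNN", c = "CCCC")
  expect_warning(
    expect_warning(m <- trainNn(seqs, c("g1", "g1", "g2"), 2), "skipping"),
    "no countable")
  expect_equal(nrow(m@profiles), 2L)
  expect_equal(m@labels, c("g1", "g2"))
})
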