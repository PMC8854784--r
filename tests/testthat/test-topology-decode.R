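test_that("one-residue likelihood matches the closed form", {
  m <- toy2_model()
  l_idx <- match("L", AA)
  expected <- log(sum(m$init * m$emis[, l_idx]))
  expect_equal(sequence_likelihood(m, "L"), expected, tolerance = 1e-12)
})

test_that("forward equals brute-force path enumeration on short sequences", {
  m <- toy3_model()
  withr::with_seed(7, {
    for (len in 1:5) {
      s <- random_aa_seq(len)
      expect_equal(sequence_likelihood(m, s), enum_loglik(m, s),
                   tolerance = 1e-9)
    }
  })
})

test_that("forward and backward recursions agree", {
  withr::with_seed(21, {
    for (i in 1:10) {
      m <- random_toy_model(sample(3:6, 1))
      s <- random_aa_seq(sample(5:60, 1))
      f <- sequence_likelihood(m, s, direction = "forward")
      b <- sequence_likelihood(m, s, direction = "backward")
      expect_equal(f, b, tolerance = 1e-9)
    }
  })
})

test_that("likelihood is invariant under consistent state relabelling", {
  m <- toy3_model()
  perm <- c(3, 1, 2)
  mp <- topology_model(m$states[perm], unname(m$labels)[perm],
                       unname(m$init)[perm], m$trans[perm, perm],
                       m$emis[perm, ], 5, 5, final = unname(m$final)[perm])
  withr::with_seed(8, {
    s <- random_aa_seq(30)
  })
  expect_equal(sequence_likelihood(m, s), sequence_likelihood(mp, s),
               tolerance = 1e-12)
})

test_that("posteriors match brute-force enumeration on short sequences", {
  m <- toy3_model()
  withr::with_seed(9, {
    for (len in c(1, 3, 5)) {
      s <- random_aa_seq(len)
      post <- posterior_decode(m, s)
      expect_equal(as.matrix(post[, c("p_in", "p_mem", "p_out")]),
                   enum_posterior(m, s), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  })
})

test_that("a model with only outside states yields p_out = 1 everywhere", {
  m <- toy_all_outside()
  post <- posterior_decode(m, "MKTAYIAK")
  expect_equal(post$p_out, rep(1, 8))
  segs <- viterbi_topology(m, "MKTAYIAK")
  expect_equal(segs, tibble::tibble(label = "outside", start = 1L, end = 8L))
})

test_that("long low-complexity sequences decode without underflow", {
  m <- default_topology_model()
  s <- paste(rep("L", 2000), collapse = "")
  post <- posterior_decode(m, s)
  expect_true(all(is.finite(attr(post, "loglik"))))
  sums <- post$p_in + post$p_mem + post$p_out
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("Viterbi path equals the enumerated maximum-probability path", {
  m <- toy3_model()
  withr::with_seed(11, {
    for (len in c(2, 4, 5)) {
      s <- random_aa_seq(len)
      segs <- viterbi_topology(m, s)
      labs <- rep(segs$label, segs$end - segs$start + 1L)
      expect_equal(labs, enum_viterbi_labels(m, s))
    }
  })
})

test_that("posterior label probabilities sum to one for random models", {
  withr::with_seed(13, {
    for (i in 1:100) {
      m <- random_toy_model(sample(3:6, 1))
      s <- random_aa_seq(sample(3:40, 1))
      post <- posterior_decode(m, s)
      expect_true(all(abs(post$p_in + post$p_mem + post$p_out - 1) < 1e-9))
      expect_true(all(post$p_in >= 0 & post$p_in <= 1))
    }
  })
})

test_that("ambiguity codes emit the background average without error", {
  m <- default_topology_model()
  expect_silent(post <- posterior_decode(m, "MKXBZUAL"))
  expect_true(all(abs(post$p_in + post$p_mem + post$p_out - 1) < 1e-9))
})

test_that("a planted hydrophobic stretch is decoded as one helix", {
  g <- generate_protein("@N-terminally anchored (no CS)", seed = 7)
  m <- default_topology_model()
  segs <- viterbi_topology(m, g$record$sequence)
  helix <- segs[segs$label == "membrane", ]
  expect_equal(nrow(helix), 1L)
  planted <- g$truth$helices
  overlap <- min(helix$end, planted$end) - max(helix$start, planted$start) + 1L
  expect_gte(overlap, 15L)
})

test_that("raising the helix emission of L never lowers p_mem on poly-L", {
  m <- default_topology_model()
  s <- paste(rep("L", 60), collapse = "")
  base <- mean(posterior_decode(m, s)$p_mem)
  m2 <- m
  core <- grepl("^h", m2$states)
  for (st in m2$states[core]) {
    row <- m2$emis[st, ]
    row["L"] <- row["L"] * 1.5
    m2$emis[st, ] <- row / sum(row)
  }
  boosted <- mean(posterior_decode(m2, s)$p_mem)
  expect_gte(boosted, base)
})

test_that("summary window statistics follow their definitions", {
  m <- toy_all_outside()
  s <- random_aa_seq(50)
  post <- posterior_decode(m, s)
  segs <- viterbi_topology(m, s)
  sm <- summarize_topology(post, segs)
  expect_equal(sm$out_first_w, 1)
  expect_equal(sm$out_last_w, 1)
  expect_equal(sm$prob_n_in, 0)
  expect_equal(sm$n_helices, 0L)

  s10 <- random_aa_seq(10)
  post10 <- posterior_decode(m, s10)
  segs10 <- viterbi_topology(m, s10)
  sm10 <- summarize_topology(post10, segs10, window = 20)
  expect_equal(sm10$out_first_w, mean(post10$p_out))  # short-sequence rule
  expect_error(summarize_topology(post10, segs10, window = 0), "window")
})

test_that("a type-II topology shows N-in and an outside C-terminal tail", {
  g <- generate_protein("@N-terminally anchored (no CS)", seed = 11)
  m <- default_topology_model()
  post <- posterior_decode(m, g$record$sequence)
  segs <- viterbi_topology(m, g$record$sequence)
  sm <- summarize_topology(post, segs)
  expect_gt(sm$prob_n_in, 0.5)
  expect_gt(sm$out_last_w, 0.5)
})

test_that("segments tile the sequence and count helices consistently", {
  m <- default_topology_model()
  withr::with_seed(15, {
    for (cls in c("@Multi-transmembrane", "@Lipid-anchored")) {
      g <- generate_protein(cls, seed = sample.int(1e6, 1))
      segs <- viterbi_topology(m, g$record$sequence)
      expect_equal(segs$start[1], 1L)
      expect_equal(segs$end[nrow(segs)], g$record$length)
      if (nrow(segs) > 1) {
        expect_equal(segs$start[-1], segs$end[-nrow(segs)] + 1L)
      }
      post <- posterior_decode(m, g$record$sequence)
      sm <- summarize_topology(post, segs)
      expect_equal(sm$n_helices, sum(segs$label == "membrane"))
    }
  })
})
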