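test_that("the stemmer reduces classic suffixes as expected", {
  expect_equal(porter_stem(c("energy", "balance", "exercise")),
               c("energi", "balanc", "exercis"))
  expect_equal(porter_stem(c("caresses", "ponies", "running", "hopeful",
                             "relational", "obesity", "activities")),
               c("caress", "poni", "run", "hope", "relat", "obes", "activ"))
})

test_that("preprocessing lowercases, strips, stems and drops empty docs", {
  prep <- suppressMessages(preprocess_abstracts(
    c("Energy balance and exercise.", "The and of a", "Sugar 123 intake!")))
  expect_equal(prep$tokens[[1]], c("energi", "balanc", "exercis"))
  expect_equal(attr(prep, "dropped"), "2")
  expect_equal(prep$tokens[[2]], c("sugar", "intak"))
  expect_error(preprocess_abstracts(c("the and", "of a")), "all abstracts empty")
})

test_that("document-frequency bounds prune the vocabulary", {
  docs <- c("sugar sugar beverage", "sugar exercise obesity",
            "sugar beverage obesity")
  prep <- preprocess_abstracts(docs, stem = FALSE, min_df = 2,
                               max_df_prop = 0.9)
  expect_false("sugar" %in% prep$vocabulary)    # in every document
  expect_false("exercise" %in% prep$vocabulary) # in only one
  expect_setequal(prep$vocabulary, c("beverage", "obesity"))
})

test_that("the topic corpus generator is deterministic and validated", {
  a <- generate_topic_corpus(20, 2, 50, 30, seed = 5)
  b <- generate_topic_corpus(20, 2, 50, 30, seed = 5)
  expect_identical(a$abstracts, b$abstracts)
  expect_error(generate_topic_corpus(10, 1, 50, 30), "k_true")
  expect_error(generate_topic_corpus(10, 2, 50, 0), "doc_length")
  # concentration 0.1 with disjoint vocabularies: most docs dominated
  tc <- generate_topic_corpus(50, 2, 100, 60, concentration = 0.1, seed = 6)
  expect_true(mean(apply(tc$truth$doc_topic, 1, max) > 0.8) > 0.6)
})

test_that("the sampler is seed-deterministic and validates inputs", {
  tc <- generate_topic_corpus(30, 2, 60, 40, seed = 2)
  corp <- list(tokens = tc$tokens, vocabulary = tc$vocabulary)
  f1 <- fit_topic_model(corp, k = 2, alpha = 0.1, iterations = 150,
                        burn_in = 50, seed = 9)
  f2 <- fit_topic_model(corp, k = 2, alpha = 0.1, iterations = 150,
                        burn_in = 50, seed = 9)
  expect_identical(f1$word_topic, f2$word_topic)
  expect_identical(f1$doc_topic, f2$doc_topic)
  expect_error(fit_topic_model(corp, k = 1), "at least 2")
  expect_error(fit_topic_model(list(tokens = tc$tokens, vocabulary = "one"),
                               k = 2), "vocabulary")
})

test_that("probability tables are normalised", {
  tc <- generate_topic_corpus(30, 3, 60, 40, seed = 3)
  fit <- fit_topic_model(list(tokens = tc$tokens, vocabulary = tc$vocabulary),
                         k = 3, alpha = 0.1, iterations = 150, burn_in = 50,
                         seed = 1)
  expect_equal(rowSums(fit$word_topic), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(rowSums(fit$doc_topic), rep(1, 30), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("dominant topic and dominance ratio follow the stated rules", {
  model <- structure(list(
    k = 3L,
    doc_topic = rbind(d1 = c(0.6, 0.3, 0.1), d2 = c(1, 1, 1) / 3),
    word_topic = matrix(1 / 4, 3, 4,
                        dimnames = list(NULL, c("a", "b", "c", "d"))),
    vocabulary = c("a", "b", "c", "d")
  ), class = "topic_model")
  a <- dominant_topic_assignment(model)
  expect_equal(a$topic, c(1L, 1L))
  expect_equal(a$ratio, c(2, 1))
  expect_true(all(a$ratio >= 1))
  s <- topic_summary(model, a)
  expect_equal(sum(s$share_pct), 100)
  expect_equal(s$share_pct[1], 100)
})

test_that("fitted topics recover a planted disjoint-vocabulary structure", {
  tc <- generate_topic_corpus(120, 2, 80, 60, concentration = 0.1, seed = 21)
  fit <- fit_topic_model(list(tokens = tc$tokens, vocabulary = tc$vocabulary),
                         k = 2, alpha = 0.1, beta = 0.01, iterations = 400,
                         burn_in = 150, seed = 22)
  phi_true <- tc$truth$word_topic[, fit$vocabulary]
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  direct <- cos(fit$word_topic[1, ], phi_true[1, ]) +
    cos(fit$word_topic[2, ], phi_true[2, ])
  crossed <- cos(fit$word_topic[1, ], phi_true[2, ]) +
    cos(fit$word_topic[2, ], phi_true[1, ])
  expect_gt(max(direct, crossed) / 2, 0.95)
  # top terms of each topic come from its own vocabulary block
  s <- topic_summary(fit, n_top = 7)
  perm <- if (direct >= crossed) 1:2 else 2:1
  for (t in 1:2) {
    own_block <- colnames(phi_true)[phi_true[perm[t], ] > 0]
    expect_true(all(names(s$top_terms[[t]]) %in% own_block))
  }
})
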