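test_that("pipe notation parses into typed layer sequences", {
  s <- "C2D | C2D | BN | DO | C2D | BN | MP | AP | MP | MP | DO | C2D | BN | F | DO | DE | BN"
  a <- parse_architecture(s)
  expect_length(a$layers, 17)
  expect_identical(vapply(a$layers, `[[`, character(1), "kind"),
                   c("C2D", "C2D", "BN", "DO", "C2D", "BN", "MP", "AP", "MP",
                     "MP", "DO", "C2D", "BN", "F", "DO", "DE", "BN"))

  single <- parse_architecture("DE")
  expect_length(single$layers, 1)
  expect_identical(single$layers[[1]]$kind, "DE")

  expect_error(parse_architecture("C2D | XX"), "XX.*position 2")
  expect_error(parse_architecture("   "), "empty")
})

test_that("format is the inverse of parse up to whitespace", {
  s <- "C2D | C2D | BN | DO | C2D | BN | MP | AP | MP | MP | DO | C2D | BN | F | DO | DE | BN"
  expect_identical(format_architecture(parse_architecture(s)), s)
  expect_identical(format_architecture(parse_architecture("DE")), "DE")
  expect_identical(format_architecture(parse_architecture("c2d|bn |f|de")),
                   "C2D | BN | F | DE")

  space <- pso_space("desk")
  for (sd in 1:20) {
    a <- random_architecture(space, input_shape = c(32, 32, 3), seed = sd)
    expect_identical(
      format_architecture(parse_architecture(format_architecture(a))),
      format_architecture(a))
  }
})

test_that("structural validation reports each broken rule with its position", {
  ok <- tdcn_pso_architecture()
  expect_length(validate_architecture(ok), 0)

  v <- validate_architecture(parse_architecture("C2D | F | DE | C2D"))
  expect_length(v, 1)
  expect_identical(v[[1]]$rule, "no_conv_after_flatten")
  expect_identical(v[[1]]$index, 4L)  # the fourth layer is the stray conv

  v2 <- validate_architecture(parse_architecture("C2D | MP"))
  expect_setequal(vapply(v2, `[[`, character(1), "rule"),
                  c("min_dense", "flatten_before_dense"))
})

test_that("repair produces feasible architectures with minimal edits", {
  r1 <- repair_architecture(parse_architecture("C2D | F | DE | C2D"))
  expect_length(validate_architecture(r1), 0)
  expect_identical(format_architecture(r1), "C2D | F | DE")

  r2 <- repair_architecture(parse_architecture("C2D | MP"))
  expect_length(validate_architecture(r2), 0)
  expect_identical(format_architecture(r2), "C2D | MP | F | DE")

  # idempotent on feasible input
  ok <- tdcn_pso_architecture()
  expect_identical(format_architecture(repair_architecture(ok)),
                   format_architecture(ok))
})

test_that("search-space cardinality matches the closed form exactly", {
  expect_identical(format(count_search_space(4, 3, 20)), "1466015503680")
  expect_identical(format(count_search_space(1, 2, 7)), "6")
  expect_identical(format(count_search_space(2, 1, 3)), "14")
  expect_error(count_search_space(4, 5, 3), "B_l")
  expect_error(count_search_space(0, 1, 2), "t_l")
})

test_that("cardinality equals exhaustive enumeration on small spaces", {
  for (t_l in 1:3) for (B_u in 1:6) for (B_l in 1:B_u) {
    expect_equal(as.numeric(count_search_space(t_l, B_l, B_u)),
                 enumerate_sequences(t_l, B_l, B_u),
                 info = sprintf("t_l=%d B_l=%d B_u=%d", t_l, B_l, B_u))
  }
})

test_that("cardinality grows strictly with the bounds and the vocabulary", {
  for (B_u in 3:8) {
    expect_true(as.numeric(count_search_space(3, 2, B_u + 1)) >
                  as.numeric(count_search_space(3, 2, B_u)))
  }
  for (t_l in 2:6) {
    expect_true(as.numeric(count_search_space(t_l + 1, 2, 5)) >
                  as.numeric(count_search_space(t_l, 2, 5)))
  }
})

test_that("parameterized-space calculus supports both readings", {
  expect_identical(
    format(count_parameterized_space(c(9, 2, 1, 4), c(12, 1, 15, 3))),
    "282429536548")  # 9^12 + 2 + 1 + 64
  expect_identical(
    format(count_parameterized_space(c(2, 3), c(1, 1), mode = "combinatorial")),
    "6")
  expect_identical(format(count_parameterized_space(c(1, 1, 1), c(5, 5, 5))), "3")
  expect_identical(
    format(count_parameterized_space(c(1, 1, 1), c(5, 5, 5), "combinatorial")),
    "1")
  expect_error(count_parameterized_space(c(2, 3), c(1, 1, 1)), "length")
})

test_that("combinatorial mode equals brute-force parameter enumeration", {
  # 2 x 3 parameter grids over one layer each: enumerate all joint choices
  grids <- list(a = 1:2, b = 1:3)
  expect_equal(as.numeric(count_parameterized_space(c(2, 3), c(1, 1),
                                                    "combinatorial")),
               nrow(expand.grid(grids)))
  # two copies of the first layer: choices multiply
  expect_equal(as.numeric(count_parameterized_space(c(2, 3), c(2, 1),
                                                    "combinatorial")),
               nrow(expand.grid(list(a1 = 1:2, a2 = 1:2, b = 1:3))))
})

test_that("training budgets are exact products", {
  expect_equal(count_models_aco(16, 32), 512)
  expect_equal(count_models_aco(1, 1), 1)
  expect_equal(count_models_aco(8, 32), 256)
  expect_error(count_models_aco(0, 4), ">= 1")
  expect_equal(count_models_pso(5, 12, 20), 1200)
  expect_equal(count_models_pso(1, 1, 1), 1)
  expect_equal(count_models_pso(2, 3, 4), 24)
  expect_error(count_models_pso(2, 0, 4), ">= 1")
})

test_that("exact big-integer arithmetic agrees with doubles in range", {
  set.seed(4)
  for (i in 1:50) {
    a <- as.numeric(sample.int(1e6, 1)); b <- as.numeric(sample.int(1e6, 1))
    expect_identical(format(big_mul(bigint(a), bigint(b))),
                     format(a * b, scientific = FALSE))
    expect_identical(format(big_add(bigint(a), bigint(b))),
                     format(a + b, scientific = FALSE))
  }
  # powers beyond 2^53 survive via the digit-string constructor
  p <- big_pow(bigint(10), 20)
  expect_identical(format(p), paste0("1", strrep("0", 20)))
  expect_true(bigint("00123") == bigint(123))
  expect_true(big_add(p, bigint(0)) == p)
})

test_that("random architectures are feasible, bounded and reproducible", {
  space <- pso_space("desk")
  for (sd in 1:30) {
    a <- random_architecture(space, input_shape = c(32, 32, 3), seed = sd)
    expect_length(validate_architecture(a), 0)
    # trunk length within bounds; BN/DO attachments and the repair pass may
    # add layers beyond the drawn trunk
    expect_gte(length(a), space$B_l)
  }
  a1 <- random_architecture(space, input_shape = c(32, 32, 3), seed = 7)
  a2 <- random_architecture(space, input_shape = c(32, 32, 3), seed = 7)
  expect_identical(format_architecture(a1), format_architecture(a2))
  expect_identical(a1$layers, a2$layers)
})

test_that("trunk layer kinds follow the configured sampling probabilities", {
  space <- pso_space("desk")
  set.seed(123)
  kinds <- swarmnas:::sample_trunk_kinds(10000, space)
  freq <- c(conv = mean(kinds == "C2D"),
            pool = mean(kinds %in% c("MP", "AP")),
            dense = mean(kinds == "DE"))
  expect_equal(unname(freq), c(0.70, 0.15, 0.15), tolerance = 0.02)
})

test_that("architecture JSON round-trips losslessly", {
  a <- tdcn_pso_architecture()
  js <- architecture_to_json(a)
  b <- architecture_from_json(js)
  expect_identical(format_architecture(b), format_architecture(a))
  expect_identical(b$input_shape, a$input_shape)
  expect_identical(b$layers, a$layers)
})
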