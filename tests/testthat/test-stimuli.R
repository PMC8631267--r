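test_that("feature spaces validate their declarations and count configurations", {
  expect_equal(n_configs(e1_space), 9L)
  expect_equal(n_configs(e2_space), 20L)
  expect_equal(n_configs(exp2_space(observed_only = TRUE)), 16L)
  expect_equal(n_configs(feature_space(list(f = c("a", "b")))), 2L)

  expect_error(feature_space(list(color = c("red", "red", "blue"))), "duplicate")
  expect_error(feature_space(list(color = "red")), "at least 2")
  expect_error(feature_space(list()), "non-empty")

  cfg <- space_configs(e1_space)
  expect_equal(nrow(cfg), 9L)
  expect_false(anyDuplicated(cfg) > 0)
  # canonical index round-trips
  for (i in c(1L, 5L, 9L))
    expect_equal(config_index(e1_space, localaws:::index_config(e1_space, i)), i)
})

test_that("one-shot designs anchor to the printed instance and reverse exactly", {
  for (seed in c(1L, 2L, 7L, 123L)) {
    d <- exp1_design("A1", "near_first", seed)
    expect_length(d$learning, 1L)
    expect_length(d$tasks, 15L)
    # printed anchor: learning red-square agent / yellow-circle recipient,
    # task 1 red-square agent / blue-circle recipient, for any seed
    expect_equal(unclass(d$learning[[1]]$agent), c(color = "red", shape = "square"))
    expect_equal(unclass(d$learning[[1]]$recipient), c(color = "yellow", shape = "circle"))
    expect_equal(unclass(d$tasks[[1]]$agent), c(color = "red", shape = "square"))
    expect_equal(unclass(d$tasks[[1]]$recipient), c(color = "blue", shape = "circle"))
    # every task carries the full 9-stone panel
    expect_true(all(vapply(d$tasks, function(t) nrow(t$panel), integer(1)) == 9L))
    # far-first is the exact reverse under the same seed
    df <- exp1_design("A1", "far_first", seed)
    expect_identical(lapply(rev(df$tasks), `[`, c("agent", "recipient")),
                     lapply(d$tasks, `[`, c("agent", "recipient")))
    # regeneration is deterministic
    expect_identical(d, exp1_design("A1", "near_first", seed))
  }
  expect_error(exp1_design("A9"), "unknown condition")
})

test_that("one-shot learning effects follow their condition specification", {
  res <- function(cond) unclass(exp1_design(cond, "near_first", 1)$learning[[1]]$result)
  expect_equal(res("A1"), c(color = "yellow", shape = "square"))  # takes agent's shape
  expect_equal(res("A2"), c(color = "yellow", shape = "diamond")) # brand-new shape
  expect_equal(res("A3"), c(color = "red", shape = "circle"))     # takes agent's color
  expect_equal(res("A4"), c(color = "blue", shape = "circle"))    # brand-new color
  expect_equal(res("A5"), c(color = "red", shape = "square"))     # both agent features
  expect_equal(res("A6"), c(color = "blue", shape = "diamond"))   # both new
})

test_that("few-shot designs are rule-consistent with full menus and catch trials", {
  cfg <- read_design_config(system.file("extdata", "exp2_design.json",
                                        package = "localaws"))
  for (cond in c("B1", "B2", "B3", "B4")) {
    d <- exp2_design(cond, seed = 5)
    expect_length(d$learning, 6L)
    expect_length(d$tasks, 18L)
    expect_equal(sum(vapply(d$tasks, `[[`, logical(1), "is_catch")), 2L)
    expect_true(all(vapply(d$tasks, function(t) nrow(t$panel), integer(1)) == 20L))
    expect_false(any(vapply(d$tasks, function(t) anyDuplicated(t$panel) > 0, logical(1))))
    # machine-check: every learning event satisfies the condition's rule
    rule <- parse_law(cfg$rules[[cfg$conditions[[cond]]$rule]])
    for (ev in d$learning)
      expect_equal(event_likelihood(ev, rule, d$space), 1)
    # fixed role really is fixed across learning events
    role <- cfg$conditions[[cond]]$fixed_role
    fixed <- vapply(d$learning, function(ev) format(ev[[role]]), character(1))
    expect_length(unique(fixed), 1L)
    expect_identical(d, exp2_design(cond, seed = 5))
  }
  expect_error(exp2_design("B9"), "unknown condition")
})

test_that("dissimilarity counts novel feature values as a set difference", {
  d <- exp2_design("B1", seed = 2)
  ds <- vapply(d$tasks, function(t) dissimilarity(t, d$learning)$DS, integer(1))
  expect_true(all(ds %in% 0:3))
  expect_true(max(ds) == 3L)   # both-novel cells reach three novel values
  # catch trials are copies of learning events: nothing novel
  catch <- vapply(d$tasks, `[[`, logical(1), "is_catch")
  expect_true(all(ds[catch] == 0L))

  # hand enumeration on a constructed instance: agent brings novel shade 4
  # and novel edge 7, recipient brings novel edge 6
  task <- generalization_task(st(shade = "4", edge = "7"),
                              st(shade = "1", edge = "6"), space = e2_space)
  expect_equal(dissimilarity(task, d$learning)$DS, 3L)
  expect_error(dissimilarity(task, list()), "non-empty")
})

test_that("design configs round-trip bit-exactly through dump and reload", {
  for (name in c("exp1_design.json", "exp2_design.json")) {
    path <- system.file("extdata", name, package = "localaws")
    cfg <- read_design_config(path)
    tmp <- tempfile(fileext = ".json")
    write_design_config(cfg, tmp)
    expect_identical(read_design_config(tmp), cfg)
  }
})
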