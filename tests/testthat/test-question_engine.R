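test_that("program executor handles the canonical cases", {
  g <- crafted_graph()
  cnt <- program(list(pnode("scene"), pnode("filter_name", "liver"),
                      pnode("count")))
  expect_identical(execute_program(cnt, g), "1")

  empty <- make_graph(data.frame(class = character(), x1 = numeric(),
                                 y1 = numeric(), x2 = numeric(),
                                 y2 = numeric()))
  ex <- program(list(pnode("scene"), pnode("filter_name", "bipolar"),
                     pnode("filter_location", "top-mid"), pnode("exist")))
  expect_identical(execute_program(ex, empty), "no")

  # unique over an ambiguous set is INVALID, and INVALID propagates
  two <- make_graph(data.frame(class = c("grasper", "grasper"),
                               x1 = c(0, 50), y1 = c(0, 50),
                               x2 = c(20, 70), y2 = c(20, 70)))
  amb <- program(list(pnode("scene"), pnode("filter_name", "grasper"),
                      pnode("unique"), pnode("query_location")))
  expect_identical(execute_program(amb, two), QA_INVALID)
})

test_that("program structural validation rejects malformed programs", {
  expect_error(program(list(pnode("scene"), pnode("filter_name", "liver"))),
               class = "surgvqa_program_error")  # non-terminal last op
  expect_error(program(list(pnode("scene"), pnode("frobnicate", "x"),
                            pnode("count"))),
               class = "surgvqa_program_error")
  expect_error(program(list(pnode("count", inputs = 1L))),
               class = "surgvqa_program_error")  # forward reference
})

test_that("tag_complexity classifies by relate count and intersect", {
  zero <- program(list(pnode("scene"), pnode("filter_name", "liver"),
                       pnode("count")))
  expect_equal(tag_complexity(zero), "zero_hop")

  one <- program(list(pnode("scene"), pnode("filter_color", "yellow"),
                      pnode("unique"), pnode("relate_spatial", "left of"),
                      pnode("unique"), pnode("query_name")))
  expect_equal(tag_complexity(one), "one_hop")

  and <- program(list(
    pnode("scene"), pnode("filter_color", "yellow"), pnode("unique"),
    pnode("relate_spatial", "left of"),
    pnode("scene", inputs = NULL),
    pnode("filter_color", "brown", inputs = 5L), pnode("unique"),
    pnode("relate_spatial", "below"),
    pnode("intersect", inputs = c(4L, 8L)), pnode("unique"),
    pnode("query_location")))
  expect_equal(tag_complexity(and), "single_and")

  three <- program(list(
    pnode("scene"), pnode("unique"), pnode("relate_spatial", "left of"),
    pnode("unique"), pnode("relate_spatial", "above"),
    pnode("unique"), pnode("relate_spatial", "below"), pnode("count")))
  expect_error(tag_complexity(three), class = "surgvqa_complexity_error")
})

test_that("executor agrees exactly with the brute-force oracle", {
  for (seed in 1:200) {
    g <- random_graph(seed)
    p <- random_program(g, seed + 10000)
    expect_identical(execute_program(p, g), oracle_execute(p, g),
                     info = paste("seed", seed))
  }
})

test_that("realize_text reproduces the canonical worked substitution", {
  reg <- load_templates()
  q <- realize_text(reg$qo1_tool_rcl_t,
                    list(R = "to the left of", C = "yellow", L = NULL,
                         T = "anatomy"))
  expect_identical(q, "what is the tool to the left of yellow anatomy?")
  # same binding twice gives the identical string
  q2 <- realize_text(reg$qo1_tool_rcl_t,
                     list(R = "to the left of", C = "yellow", L = NULL,
                          T = "anatomy"))
  expect_identical(q, q2)
})

test_that("null slots realize by rule: location->'in the frame', type->'thing'", {
  reg <- load_templates()
  expect_identical(realize_text(reg$cnt0_inst_loc, list(L = NULL)),
                   "how many instruments are in the frame?")
  expect_identical(realize_text(reg$cnt0_inst_loc, list(L = "top-mid")),
                   "how many instruments are in the top-mid location?")
  expect_identical(
    realize_text(reg$qo1_tool_rcl_t,
                 list(R = "above", C = NULL, L = NULL, T = NULL)),
    "what is the tool above thing?")
  expect_error(realize_text(reg$qo1_tool_rcl_t,
                            list(R = NULL, C = "yellow", L = NULL,
                                 T = "anatomy")),
               class = "surgvqa_binding_error")
})

test_that("instantiate on the crafted graph answers 'hook' for the tool query", {
  reg <- load_templates()
  g <- crafted_graph()
  qas <- instantiate(reg$qo1_tool_rcl_t, g)
  expect_gt(length(qas), 0)
  hit <- Filter(function(q) {
    q$question == "what is the tool to the left of yellow anatomy?"
  }, qas)
  expect_equal(length(hit), 1)
  expect_identical(hit[[1]]$answer, "hook")
})

test_that("every emitted QA pair is sound and answer-closed", {
  g <- crafted_graph()
  qa <- generate_for_scene(g, list(cap = 60), seed = 5)
  vocab_ok <- answer_vocabulary()
  reg <- load_templates()
  for (q in qa) {
    expect_identical(execute_program(q$program, g), q$answer)
    expect_true(q$answer %in% vocab_ok)
    expect_identical(realize_text(reg[[q$template_id]], q$binding),
                     q$question)
  }
})

test_that("generate_for_scene respects the cap and is seed-deterministic", {
  g <- crafted_graph()
  qa <- generate_for_scene(g, list(cap = 10), seed = 9)
  expect_lte(length(qa), 10)
  expect_identical(generate_for_scene(g, list(cap = 10), seed = 9), qa)
  expect_equal(length(generate_for_scene(g, list(cap = 0), seed = 9)), 0)
})

test_that("an empty graph yields only existence/counting questions with no/0", {
  empty <- make_graph(data.frame(class = character(), x1 = numeric(),
                                 y1 = numeric(), x2 = numeric(),
                                 y2 = numeric()))
  qa <- generate_for_scene(empty, list(cap = 50), seed = 2)
  expect_gt(length(qa), 0)
  for (q in qa) {
    expect_true(q$qtype %in% c("existence", "counting"))
    expect_true(q$answer %in% c("no", "0"))
  }
})

test_that("generation on the standard fixture reaches all qtypes and complexities", {
  proc <- random_procedure(fixture_config(n_frames = 21, seed = 3))
  qa <- list()
  for (fid in names(proc$graphs)[seq(1, 21, by = 4)]) {
    qa <- c(qa, generate_for_scene(proc$graphs[[fid]], list(cap = 200),
                                   seed = 4))
  }
  qtypes <- unique(vapply(qa, function(q) q$qtype, character(1)))
  cpx <- unique(vapply(qa, function(q) q$complexity, character(1)))
  expect_setequal(qtypes, c("query_object", "query_attribute",
                            "query_relation", "existence", "counting"))
  expect_setequal(cpx, c("zero_hop", "one_hop", "single_and"))
})
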