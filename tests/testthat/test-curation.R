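make_timeline <- function(counts) {
  frames <- character(); phases <- character()
  for (ph in names(counts)) {
    ids <- sprintf("%s-%03d", ph, seq_len(counts[[ph]]))
    frames <- c(frames, ids)
    phases <- c(phases, rep(ph, counts[[ph]]))
  }
  list(frames = frames,
       timeline = stats::setNames(phases, frames))
}

test_that("phase balancing trims overrepresented phases to the minimum", {
  tl <- make_timeline(c(preparation = 100,
                        `calot-triangle-dissection` = 10,
                        `clipping-and-cutting` = 10))
  sel <- phase_balanced_sample(tl$frames, tl$timeline,
                               curation_config(tolerance = 0), seed = 1)
  expect_equal(length(sel), 30)
  per <- table(tl$timeline[sel])
  expect_true(all(per == 10))
})

test_that("already-balanced inputs are retained in full; tolerance widens the band", {
  tl <- make_timeline(c(preparation = 8, `gallbladder-dissection` = 8))
  sel <- phase_balanced_sample(tl$frames, tl$timeline, seed = 3)
  expect_setequal(sel, tl$frames)

  tl2 <- make_timeline(c(preparation = 12, `gallbladder-dissection` = 5))
  sel2 <- phase_balanced_sample(tl2$frames, tl2$timeline,
                                curation_config(tolerance = 3), seed = 3)
  per <- table(tl2$timeline[sel2])
  expect_equal(unname(per["preparation"]), 8)  # min 5 + tolerance 3
  expect_equal(unname(per["gallbladder-dissection"]), 5)
})

test_that("phase balancing is seed-deterministic and never drops a phase", {
  set.seed(99)
  for (i in 1:10) {
    counts <- stats::setNames(sample(1:40, 4),
                              c("preparation", "calot-triangle-dissection",
                                "gallbladder-dissection",
                                "cleaning-and-coagulation"))
    tl <- make_timeline(as.list(counts))
    s1 <- phase_balanced_sample(tl$frames, tl$timeline, seed = i)
    s2 <- phase_balanced_sample(tl$frames, tl$timeline, seed = i)
    expect_identical(s1, s2)
    per <- table(tl$timeline[s1])
    expect_setequal(names(per), names(counts))
    m <- min(counts)
    expect_true(all(per >= pmin(counts[names(per)], m)))
    expect_true(all(per <= m))  # tolerance 0
  }
  expect_equal(phase_balanced_sample(character(), c(a = "preparation")),
               character())
})

test_that("blocklist removes templates; default blocks anatomy counting", {
  reg <- load_templates()
  kept <- apply_blocklist(reg, curation_config())
  expect_false("cnt0_name_any" %in% names(kept))
  # no retained template can realize the anatomy-count question
  g <- crafted_graph()
  pool <- list()
  for (tp in kept) pool <- c(pool, instantiate(tp, g))
  qs <- vapply(pool, function(q) q$question, character(1))
  expect_false(any(grepl("how many livers are there", qs)))

  expect_identical(apply_blocklist(reg, list(blocklist = character())), reg)
  expect_equal(length(apply_blocklist(reg, list(blocklist = names(reg)))), 0)
  expect_error(apply_blocklist(reg, list(blocklist = "no_such_template")),
               class = "surgvqa_config_error")
})

test_that("degenerate filter drops absent referents, anatomy counts and INVALIDs", {
  reg <- load_templates()
  g_with <- crafted_graph()
  g_without <- make_graph(data.frame(class = c("hook", "liver"),
                                     x1 = c(5, 42), y1 = c(42, 2),
                                     x2 = c(25, 62), y2 = c(58, 22)),
                          frame_id = "f2")
  loc_q <- surgvqa:::qa_pair(
    "what is the location of the gallbladder?", "mid-mid",
    reg$qa0_loc_name, list(N = "gallbladder"),
    surgvqa:::bind_program(reg$qa0_loc_name, list(N = "gallbladder")), "f2")
  cnt_q <- surgvqa:::qa_pair(
    "how many livers are there?", "1",
    reg$cnt0_name_any, list(N = "liver"),
    surgvqa:::bind_program(reg$cnt0_name_any, list(N = "liver")), "f2")
  good <- instantiate(reg$qo1_tool_rcl_t, g_with)[[1]]

  graphs <- list(f1 = g_with, f2 = g_without)
  kept <- degenerate_filter(list(loc_q, cnt_q, good), graphs)
  expect_equal(length(kept), 1)
  expect_identical(kept[[1]]$question, good$question)
  # idempotence
  expect_identical(degenerate_filter(kept, graphs), kept)
})

test_that("degenerate filter matches an independent re-check of its rules", {
  proc <- random_procedure(fixture_config(n_frames = 14, seed = 8))
  g <- proc$graphs[[3]]
  qa <- generate_for_scene(g, list(cap = 120), seed = 6)
  kept <- degenerate_filter(qa, proc$graphs)
  anat <- load_vocab()$anatomies
  recheck <- Filter(function(q) {
    ans <- oracle_execute(q$program, proc$graphs[[q$frame_id]])
    if (identical(ans, "__INVALID__")) return(FALSE)
    names_in_prog <- unlist(lapply(q$program, function(nd) {
      if (nd$op == "filter_name") nd$arg else NULL
    }))
    if (q$qtype == "counting") {
      types_in_prog <- unlist(lapply(q$program, function(nd) {
        if (nd$op == "filter_type") nd$arg else NULL
      }))
      if (any(names_in_prog %in% anat) || "anatomy" %in% types_in_prog) {
        return(FALSE)
      }
    }
    if (q$qtype %in% c("query_object", "query_attribute", "query_relation")) {
      present <- vapply(proc$graphs[[q$frame_id]]$objects,
                        function(o) o$name, character(1))
      if (!all(names_in_prog %in% present)) return(FALSE)
    }
    TRUE
  }, qa)
  expect_identical(vapply(kept, function(q) q$question, character(1)),
                   vapply(recheck, function(q) q$question, character(1)))
})

test_that("answer rebalancing enforces the per-type frequency cap", {
  mk <- function(ans, qt = "existence") {
    structure(list(question = paste("q", seq_along(ans)), answer = ans[1],
                   template_id = "t", binding = list(), program = NULL,
                   frame_id = "f", qtype = qt, complexity = "zero_hop"),
              class = "surgvqa_qa")
  }
  pool <- c(lapply(1:90, function(i) mk("yes")),
            lapply(1:10, function(i) mk("no")))
  out <- answer_rebalance(pool, curation_config(answer_cap = 0.6), seed = 4)
  frac_yes <- mean(vapply(out, function(q) q$answer, character(1)) == "yes")
  expect_lte(frac_yes, 0.6)
  expect_equal(sum(vapply(out, function(q) q$answer, character(1)) == "no"), 10)

  # under the cap: untouched
  pool2 <- c(lapply(1:5, function(i) mk("yes")),
             lapply(1:5, function(i) mk("no")))
  expect_identical(answer_rebalance(pool2, curation_config(answer_cap = 0.6),
                                    seed = 4), pool2)
  # single-answer pools are exempt
  pool3 <- lapply(1:20, function(i) mk("yes"))
  expect_identical(answer_rebalance(pool3, curation_config(answer_cap = 0.6),
                                    seed = 4), pool3)
})
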