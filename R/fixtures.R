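# Seed-deterministic synthetic laparoscopic-cholecystectomy streams: phase
# timelines laid out as contiguous blocks with skewed durations, temporally
# coherent objects (boxes jittered across adjacent frames), one action
# triplet per frame with a phase-conditioned verb, and purpose-built QA
# datasets for the bias audit.

PHASE_VERBS <- list(
  "preparation" = c("grasp", "retract"),
  "calot-triangle-dissection" = "dissect",
  "clipping-and-cutting" = c("clip", "cut"),
  "gallbladder-dissection" = c("dissect", "coagulate"),
  "gallbladder-packaging" = "grasp",
  "cleaning-and-coagulation" = c("coagulate", "aspirate", "irrigate"),
  "gallbladder-retraction" = c("retract", "grasp")
)

PHASE_INSTRUMENTS <- list(
  "preparation" = c(grasper = 0.9, hook = 0.2),
  "calot-triangle-dissection" = c(grasper = 0.8, hook = 0.9),
  "clipping-and-cutting" = c(clipper = 0.9, scissors = 0.7, grasper = 0.6),
  "gallbladder-dissection" = c(hook = 0.9, grasper = 0.7),
  "gallbladder-packaging" = c(grasper = 0.95),
  "cleaning-and-coagulation" = c(bipolar = 0.8, irrigator = 0.7),
  "gallbladder-retraction" = c(grasper = 0.95)
)

PHASE_TARGETS <- list(
  "preparation" = c("gallbladder", "liver"),
  "calot-triangle-dissection" = c("cystic-duct", "gallbladder"),
  "clipping-and-cutting" = c("cystic-duct", "gallbladder"),
  "gallbladder-dissection" = c("gallbladder", "liver"),
  "gallbladder-packaging" = "gallbladder",
  "cleaning-and-coagulation" = c("liver", "abdominal-wall-cavity"),
  "gallbladder-retraction" = c("gallbladder", "liver")
)

#' Default synthetic-procedure configuration
#'
#' The defaults emulate the structure of a cholecystectomy stream: 7 phases
#' in canonical order with skewed durations (preparation and Calot-triangle
#' dissection overrepresented, as they are in real timelines), the liver
#' visible in every frame, each anatomy at most once per frame, instruments
#' appearing with phase-typical probabilities, and one triplet per frame.
#'
#' @param n_frames number of frames (default 140).
#' @param frame_dims frame `c(width, height)` in pixels (default 854 x 480,
#'   the usual laparoscopic video resolution).
#' @param phase_weights positive duration weights over the 7 phases.
#' @param anatomy_probs named per-class presence probability per phase block.
#' @param jitter_sd Gaussian centroid jitter between adjacent frames, pixels.
#' @param seed integer seed.
#' @return list of class `surgvqa_fixture_config`.
#' @export
fixture_config <- function(n_frames = 140L,
                           frame_dims = c(854, 480),
                           phase_weights = c(4, 6, 2, 3, 1, 2, 1),
                           anatomy_probs = c("liver" = 1.0,
                                             "gallbladder" = 0.95,
                                             "abdominal-wall-cavity" = 0.6,
                                             "gut" = 0.25,
                                             "omentum" = 0.35,
                                             "cystic-duct" = 0.3,
                                             "peritoneum" = 0.3),
                           jitter_sd = 12,
                           seed = 1L) {
  if (n_frames < 1) {
    abort_surgvqa("n_frames must be >= 1", "surgvqa_config_error")
  }
  if (length(phase_weights) != 7 || any(phase_weights <= 0)) {
    abort_surgvqa("phase_weights must be 7 positive values",
                  "surgvqa_config_error")
  }
  if (any(anatomy_probs < 0 | anatomy_probs > 1)) {
    abort_surgvqa("anatomy probabilities must lie in [0, 1]",
                  "surgvqa_config_error")
  }
  structure(list(n_frames = as.integer(n_frames), frame_dims = frame_dims,
                 phase_weights = phase_weights, anatomy_probs = anatomy_probs,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "surgvqa_fixture_config")
}

# proportional apportionment with largest remainders; every phase >= 1 frame
apportion <- function(n, weights) {
  raw <- n * weights / sum(weights)
  base <- pmax(floor(raw), 1)
  while (sum(base) > n) base[which.max(base)] <- base[which.max(base)] - 1
  rem <- raw - base
  while (sum(base) < n) {
    i <- which.max(rem)
    base[i] <- base[i] + 1
    rem[i] <- -Inf
  }
  as.integer(base)
}

sample_box <- function(frame_dims, size_range_w, size_range_h) {
  w <- stats::runif(1, size_range_w[1], size_range_w[2])
  h <- stats::runif(1, size_range_h[1], size_range_h[2])
  x1 <- stats::runif(1, 0, frame_dims[1] - w)
  y1 <- stats::runif(1, 0, frame_dims[2] - h)
  c(x1, y1, x1 + w, y1 + h)
}

jitter_box <- function(b, frame_dims, sd) {
  w <- b[3] - b[1]; h <- b[4] - b[2]
  cx <- (b[1] + b[3]) / 2 + stats::rnorm(1, 0, sd)
  cy <- (b[2] + b[4]) / 2 + stats::rnorm(1, 0, sd)
  cx <- min(max(cx, w / 2), frame_dims[1] - w / 2)
  cy <- min(max(cy, h / 2), frame_dims[2] - h / 2)
  c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

#' Generate a synthetic surgical procedure
#'
#' Lays phases out as contiguous blocks proportional to the duration
#' weights. Within a block the same objects persist with per-frame Gaussian
#' box jitter; each frame carries exactly one action triplet linking a
#' present instrument to a present, phase-typical anatomy with a
#' phase-conditioned verb. Pure function of the config (identical seeds give
#' identical output).
#'
#' @param config a [fixture_config()].
#' @param vocab vocabulary config.
#' @return list with `timeline` (data.frame frame_id, phase), `graphs`
#'   (named list of `surgvqa_graph`), `detections` and `triplets`
#'   (data.frames in the interchange format).
#' @export
random_procedure <- function(config = fixture_config(), vocab = load_vocab()) {
  with_seed(config$seed, {
    phases <- vocab$phases
    counts <- apportion(config$n_frames, config$phase_weights)
    frame_ids <- sprintf("frame-%04d", seq_len(config$n_frames))
    phase_of <- rep(phases, counts)
    graphs <- list()
    det_rows <- list()
    trip_rows <- list()
    fi <- 0L
    for (p in seq_along(phases)) {
      ph <- phases[p]
      # block-level presence draws (objects persist through the block)
      anat <- names(config$anatomy_probs)[
        stats::runif(length(config$anatomy_probs)) < config$anatomy_probs]
      iprobs <- PHASE_INSTRUMENTS[[ph]]
      inst <- names(iprobs)[stats::runif(length(iprobs)) < iprobs]
      if (!length(inst)) inst <- names(iprobs)[which.max(iprobs)]
      # a frequent instrument may appear twice (second instance)
      dup <- inst[iprobs[inst] >= 0.9 & stats::runif(length(inst)) < 0.3]
      classes <- c(anat, inst, dup)
      base_boxes <- lapply(classes, function(cl) {
        if (cl %in% vocab$anatomies) {
          sample_box(config$frame_dims, c(150, 350), c(120, 260))
        } else {
          sample_box(config$frame_dims, c(90, 200), c(50, 140))
        }
      })
      verb <- sample(PHASE_VERBS[[ph]], 1)
      pref <- PHASE_TARGETS[[ph]]
      target <- c(intersect(pref, anat), intersect("liver", anat), anat)[1]
      actor <- sort(inst)[1]
      for (f in seq_len(counts[p])) {
        fi <- fi + 1L
        fid <- frame_ids[fi]
        boxes <- lapply(base_boxes, jitter_box,
                        frame_dims = config$frame_dims, sd = config$jitter_sd)
        det <- data.frame(
          frame_id = fid, class = classes,
          x1 = vapply(boxes, `[`, numeric(1), 1),
          y1 = vapply(boxes, `[`, numeric(1), 2),
          x2 = vapply(boxes, `[`, numeric(1), 3),
          y2 = vapply(boxes, `[`, numeric(1), 4),
          score = 1.0, stringsAsFactors = FALSE)
        trip <- data.frame(frame_id = fid, instrument_class = actor,
                           verb = verb, target_class = target,
                           stringsAsFactors = FALSE)
        graphs[[fid]] <- build_scene_graph(
          det, trip, config$frame_dims, vocab, frame_id = fid)
        det_rows[[fi]] <- det
        trip_rows[[fi]] <- trip
      }
    }
    list(timeline = data.frame(frame_id = frame_ids, phase = phase_of,
                               stringsAsFactors = FALSE),
         graphs = graphs,
         detections = do.call(rbind, det_rows),
         triplets = do.call(rbind, trip_rows))
  })
}

#' Build a deliberately leaky QA dataset
#'
#' Emits, for every anatomy present in every graph, questions whose answer
#' is a deterministic function of the question text: anatomy counts (always
#' "1", mirroring "how many livers are there?"), per-class colors (a fixed
#' lookup) and existence of present anatomies (always "yes"). A text-only
#' probe can reach perfect held-out accuracy on this family without any
#' visual input.
#'
#' @param graphs named list of `surgvqa_graph` (e.g. from
#'   [random_procedure()]).
#' @param vocab vocabulary config.
#' @return list of `surgvqa_qa` with stored programs (re-executable on the
#'   graphs).
#' @export
leaky_dataset <- function(graphs, vocab = load_vocab()) {
  reg <- load_templates()
  out <- list()
  for (g in graphs) {
    anames <- sort(unique(vapply(g$objects, function(o) o$name, character(1))))
    anames <- intersect(anames, vocab$anatomies)
    for (nm in anames) {
      cnt_b <- list(N = nm)
      col_b <- list(N = nm)
      ex_b <- list(N = nm, L = NULL)
      specs <- list(
        list(tpl = reg$cnt0_name_any, b = cnt_b),
        list(tpl = reg$qa0_color_name, b = col_b),
        list(tpl = reg$ex0_name_loc, b = ex_b))
      for (sp in specs) {
        prog <- bind_program(sp$tpl, sp$b)
        ans <- execute_program(prog, g)
        if (identical(ans, QA_INVALID)) next
        out[[length(out) + 1]] <- qa_pair(
          realize_text(sp$tpl, sp$b), ans, sp$tpl, sp$b, prog, g$frame_id)
      }
    }
  }
  out
}

#' Build a balanced (bias-free) QA dataset
#'
#' Answers are drawn uniformly within each question type, independent of the
#' question text given the type, so no text-only probe can beat the chance
#' rate implied by the answer marginals. Question strings are synthetic
#' identifiers; programs are absent (the dataset exists purely to calibrate
#' the bias audit).
#'
#' @param n number of QA pairs.
#' @param qtype_answers named list: question type -> candidate answer set.
#' @param n_questions number of distinct question strings per type.
#' @param seed integer seed.
#' @return list of `surgvqa_qa`-shaped records.
#' @export
balanced_dataset <- function(n = 2000L,
                             qtype_answers = list(
                               query_attribute = c("yellow", "brown",
                                                   "pink", "red")),
                             n_questions = 200L,
                             seed = 1L) {
  if (n == 0) return(list())
  with_seed(seed, {
    qts <- sample(names(qtype_answers), n, replace = TRUE)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      qt <- qts[i]
      ans <- sample(qtype_answers[[qt]], 1)
      j <- sample.int(n_questions, 1)
      out[[i]] <- structure(list(
        question = sprintf("balanced probe question %s number %d", qt, j),
        answer = ans, template_id = "synthetic-balanced",
        binding = list(), program = NULL,
        frame_id = "synthetic", qtype = qt,
        complexity = "zero_hop"), class = "surgvqa_qa")
    }
    out
  })
}
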