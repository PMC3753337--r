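#' Junction specification for rearrangement planning
#'
#' Controls how the junction between two joined fragments is built:
#' the class mix (microhomology, blunt, untemplated insertion, genomic
#' shard, templated insertion of nearby sequence) and the length
#' distributions within each class.
#'
#' @param type_probs Named probabilities over junction classes
#'   `microhomology`, `blunt`, `insertion`, `shard`, `templated`. The
#'   default mix follows the spectrum typically seen at somatic junctions:
#'   microhomology-dominated, with a minority of blunt joins and rare
#'   inserted fragments.
#' @param mh_lengths Candidate microhomology lengths (bp).
#' @param mh_probs Optional weights over `mh_lengths`; default is a
#'   geometric-like decay favouring short homologies.
#' @param ins_lengths Candidate untemplated-insertion lengths (bp).
#' @param frag_length Range (min, max) of inserted-fragment length for
#'   shard/templated junctions (bp). Kept short enough to sit inside a
#'   Sanger-length junction read.
#' @param shard_min Distance threshold (bp) separating a templated
#'   insertion of nearby sequence (donor within `shard_min` of a
#'   breakpoint) from a genomic shard (donor farther away).
#' @return A list of class `sv_junction_config`.
#' @export
junction_config <- function(type_probs = c(microhomology = 0.62,
                                           blunt = 0.22,
                                           insertion = 0.10,
                                           shard = 0.03,
                                           templated = 0.03),
                            mh_lengths = 1:28,
                            mh_probs = NULL,
                            ins_lengths = 1:17,
                            frag_length = c(30, 80),
                            shard_min = 1e4) {
  classes <- c("microhomology", "blunt", "insertion", "shard", "templated")
  probs <- setNames(rep(0, 5), classes)
  assert_that(all(names(type_probs) %in% classes),
              "unknown junction class in `type_probs`.")
  probs[names(type_probs)] <- type_probs
  probs <- probs / sum(probs)
  if (is.null(mh_probs)) mh_probs <- 0.75^mh_lengths
  mh_probs <- mh_probs / sum(mh_probs)
  structure(
    list(type_probs = probs, mh_lengths = mh_lengths, mh_probs = mh_probs,
         ins_lengths = ins_lengths, frag_length = frag_length,
         shard_min = shard_min),
    class = "sv_junction_config"
  )
}

draw_junction_specs <- function(n, config) {
  type <- sample(names(config$type_probs), n, replace = TRUE,
                 prob = config$type_probs)
  mh <- ifelse(type == "microhomology",
               sample(rep(config$mh_lengths, 2), n, replace = TRUE,
                      prob = rep(config$mh_probs, 2)), 0L)
  ins_len <- ifelse(type == "insertion",
                    sample(rep(config$ins_lengths, 2), n, replace = TRUE), 0L)
  tibble(type = type, mh_len = as.integer(mh), ins_len = as.integer(ins_len))
}

#' Plan genomic rearrangements
#'
#' Builds rearrangement plans against a genome, either as independent
#' simple events (deletions, inversions, tandem duplications and
#' unbalanced translocations, all larger than 50 kb by default) or as a
#' chromothripsis event that shatters one designated chromosome into at
#' least `2 * n_events` fragments, retains a random subset and reassembles
#' it in random order and orientation. With a diploid rendering (one
#' intact homolog retained) the chromothriptic chromosome oscillates
#' between exactly two copy states, one and two.
#'
#' @param genome An `sv_genome`.
#' @param mode `"simple"` or `"chromothripsis"`.
#' @param n_events Number of simple events, or half the number of
#'   chromothripsis fragments.
#' @param junction_spec An [junction_config()] object controlling the
#'   junction classes planted between joined fragments.
#' @param seed Integer seed.
#' @param target_chrom Chromosome to shatter in chromothripsis mode
#'   (default: the first chromosome).
#' @param sv_types Simple-mode event types to draw from.
#' @param size_range Range of simple-event sizes in bp, drawn log-uniform
#'   (default 50 kb to 5 Mb, capped by chromosome size).
#' @param min_segment Minimum chromothripsis fragment length (bp).
#' @param keep_prob Probability that a chromothripsis fragment is
#'   retained in the derivative chromosome.
#' @return A list of `sv_plan` objects. Each holds `events`, the derived
#'   chromosome `assembly` (ordered segments with orientation), the
#'   planned `junctions`, the chromosomes it replaces, and (for
#'   chromothripsis) the true copy-state table `states`.
#' @export
plan_rearrangements <- function(genome,
                                mode = c("simple", "chromothripsis"),
                                n_events,
                                junction_spec = junction_config(),
                                seed,
                                target_chrom = NULL,
                                sv_types = c("deletion", "inversion",
                                             "duplication", "translocation"),
                                size_range = c(5e4, 5e6),
                                min_segment = 5e3,
                                keep_prob = 0.5) {
  mode <- match.arg(mode)
  assert_that(n_events >= 1, "`n_events` must be >= 1.")
  lens <- genome_lengths(genome)
  with_seed(seed, {
    if (mode == "chromothripsis") {
      target_chrom <- target_chrom %||% names(lens)[1]
      list(plan_chromothripsis(genome, target_chrom, n_events,
                               junction_spec, min_segment, keep_prob))
    } else {
      plan_simple(genome, n_events, junction_spec, sv_types, size_range)
    }
  })
}

# margin kept clear around breakpoints and chromosome ends
BP_MARGIN <- 200L

plan_simple <- function(genome, n_events, config, sv_types, size_range) {
  lens <- genome_lengths(genome)
  types <- sample(rep(sv_types, 2), n_events, replace = TRUE)
  # translocations claim two exclusive chromosomes; intra events share
  free <- names(lens)
  events <- vector("list", n_events)
  intra_regions <- lapply(lens, function(...) IRanges::IRanges())
  intra_chroms <- character(0)
  for (i in seq_len(n_events)) {
    t <- types[i]
    if (t == "translocation") {
      avail <- setdiff(free, intra_chroms)
      # a translocation consumes two chromosomes; keep one for any
      # remaining intra-chromosomal events
      if (length(avail) < 2 || (i < n_events && length(free) < 3)) {
        t <- sample(setdiff(sv_types, "translocation"), 1)
        types[i] <- t
      }
    }
    if (t != "translocation" && length(free) == 0) {
      abort("chromosome too short for requested events.")
    }
    if (t == "translocation") {
      avail <- setdiff(free, intra_chroms)
      ch <- sample(avail, 2)
      free <- setdiff(free, ch)
      a <- sample(seq(BP_MARGIN, lens[[ch[1]]] - BP_MARGIN), 1)
      b <- sample(seq(BP_MARGIN, lens[[ch[2]]] - BP_MARGIN), 1)
      events[[i]] <- tibble(event_id = sprintf("ev%02d", i), type = t,
                            chrom = ch[1], start = a, end = NA_integer_,
                            chrom2 = ch[2], pos2 = b)
    } else {
      placed <- FALSE
      for (try in 1:200) {
        ch <- sample(free, 1)
        hi <- min(size_range[2], floor((lens[[ch]] - 2 * BP_MARGIN) * 0.6))
        if (hi <= size_range[1]) next
        size <- round(exp(runif(1, log(size_range[1]), log(hi))))
        lo <- BP_MARGIN
        up <- lens[[ch]] - size - BP_MARGIN
        if (up <= lo) next
        a <- sample(seq(lo, up), 1)
        cand <- IRanges::IRanges(a - BP_MARGIN, a + size + BP_MARGIN)
        if (length(IRanges::findOverlaps(cand, intra_regions[[ch]])) > 0) next
        intra_regions[[ch]] <- c(intra_regions[[ch]], cand)
        intra_chroms <- union(intra_chroms, ch)
        events[[i]] <- tibble(event_id = sprintf("ev%02d", i), type = t,
                              chrom = ch, start = a, end = a + size - 1L,
                              chrom2 = NA_character_, pos2 = NA_integer_)
        placed <- TRUE
        break
      }
      if (!placed) abort("chromosome too short for requested events.")
    }
  }
  events <- bind_rows(events)
  plans <- list()
  # one derivative per affected chromosome (intra) or chromosome pair
  for (ch in unique(events$chrom[events$type != "translocation"])) {
    ev <- events |>
      filter(.data$chrom == ch, .data$type != "translocation") |>
      arrange(.data$start)
    plans[[length(plans) + 1]] <-
      build_intra_plan(ch, lens[[ch]], ev, config, genome)
  }
  for (i in which(events$type == "translocation")) {
    ev <- events[i, ]
    plans[[length(plans) + 1]] <-
      build_translocation_plan(ev, lens, config, genome)
  }
  plans
}

# Draw the concrete junction payloads (untemplated insertion sequences,
# shard/templated fragment coordinates) at planning time so rendering is
# fully deterministic given the plan.
finalize_junction_details <- function(junctions, assembly, genome, config) {
  lens <- genome_lengths(genome)
  bf <- base_frequencies(genome)
  ctx <- tibble(chrom = rep(assembly$chrom, 2),
                pos = c(assembly$start, assembly$end))
  clear_of_context <- function(ch, lo, hi) {
    hits <- ctx$chrom == ch & ctx$pos >= lo - 100 & ctx$pos <= hi + 100
    !any(hits)
  }
  n <- nrow(junctions)
  ins_seq <- rep(NA_character_, n)
  frag_chrom <- rep(NA_character_, n)
  frag_start <- rep(NA_integer_, n)
  frag_end <- rep(NA_integer_, n)
  frag_orient <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    j <- junctions[k, ]
    if (j$type == "insertion") {
      ins_seq[k] <- random_dna(j$ins_len, bf)
    } else if (j$type %in% c("shard", "templated")) {
      segL <- assembly[j$after_seg, ]
      segR <- assembly[j$after_seg + 1L, ]
      bpA <- if (segL$orient == "+") segL$end else segL$start
      bpB <- if (segR$orient == "+") segR$start else segR$end
      fl <- sample(seq(config$frag_length[1], config$frag_length[2]), 1)
      placed <- FALSE
      for (try in 1:100) {
        if (j$type == "shard") {
          ch <- sample(names(lens), 1)
          if (lens[[ch]] < fl + 2L * BP_MARGIN) next
          fs <- sample(seq(BP_MARGIN, lens[[ch]] - fl - BP_MARGIN), 1)
          fe <- fs + fl - 1L
          d <- Inf
          if (ch == segL$chrom) d <- min(d, abs(c(fs, fe) - bpA))
          if (ch == segR$chrom) d <- min(d, abs(c(fs, fe) - bpB))
          if (d <= config$shard_min) next
        } else {
          ch <- segL$chrom
          off_max <- config$shard_min - fl - 150L
          if (off_max < 200L) next
          off <- sample(200:off_max, 1)
          side <- sample(c(-1L, 1L), 1)
          fs <- if (side > 0) bpA + off else bpA - off - fl + 1L
          fe <- fs + fl - 1L
          if (fs < BP_MARGIN || fe > lens[[ch]] - BP_MARGIN) next
        }
        if (!clear_of_context(ch, fs, fe)) next
        frag_chrom[k] <- ch
        frag_start[k] <- fs
        frag_end[k] <- fe
        frag_orient[k] <- sample(c("+", "-"), 1)
        placed <- TRUE
        break
      }
      if (!placed) abort("junction spec conflicts (cannot place fragment).")
    }
  }
  junctions |>
    mutate(ins_seq = ins_seq, frag_chrom = frag_chrom,
           frag_start = frag_start, frag_end = frag_end,
           frag_orient = frag_orient)
}

build_intra_plan <- function(chrom, len, events, config, genome) {
  der <- paste0("der_", chrom)
  segs <- list()
  juncs <- list()
  cursor <- 1L
  push_seg <- function(s, e, o) {
    segs[[length(segs) + 1]] <<- tibble(chrom = chrom, start = as.integer(s),
                                        end = as.integer(e), orient = o)
  }
  push_junc <- function(event_id) {
    juncs[[length(juncs) + 1]] <<- tibble(after_seg = length(segs),
                                          event_id = event_id)
  }
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (ev$type == "deletion") {
      push_seg(cursor, ev$start - 1L, "+"); push_junc(ev$event_id)
      cursor <- ev$end + 1L
    } else if (ev$type == "inversion") {
      push_seg(cursor, ev$start - 1L, "+"); push_junc(ev$event_id)
      push_seg(ev$start, ev$end, "-"); push_junc(ev$event_id)
      cursor <- ev$end + 1L
    } else if (ev$type == "duplication") {
      push_seg(cursor, ev$end, "+"); push_junc(ev$event_id)
      cursor <- ev$start
    }
  }
  push_seg(cursor, len, "+")
  assembly <- bind_rows(segs) |>
    mutate(der_chrom = der, seg_order = row_number(), .before = 1)
  jt <- bind_rows(juncs)
  specs <- draw_junction_specs(nrow(jt), config)
  junctions <- bind_cols(jt, specs) |>
    mutate(der_chrom = der, junction_id = sprintf("%s_j%d", der, row_number())) |>
    finalize_junction_details(assembly, genome, config)
  structure(list(mode = "simple", events = events, assembly = assembly,
                 junctions = junctions, replaced = chrom, states = NULL,
                 shattered_chrom = NULL, config = config),
            class = "sv_plan")
}

build_translocation_plan <- function(ev, lens, config, genome) {
  der <- paste0("der_", ev$chrom)
  assembly <- tibble(
    der_chrom = der, seg_order = 1:2,
    chrom = c(ev$chrom, ev$chrom2),
    start = c(1L, ev$pos2),
    end = c(ev$start, lens[[ev$chrom2]]),
    orient = c("+", "+")
  )
  specs <- draw_junction_specs(1, config)
  junctions <- bind_cols(tibble(after_seg = 1L, event_id = ev$event_id),
                         specs) |>
    mutate(der_chrom = der, junction_id = sprintf("%s_j1", der)) |>
    finalize_junction_details(assembly, genome, config)
  structure(list(mode = "simple", events = ev, assembly = assembly,
                 junctions = junctions,
                 replaced = c(ev$chrom, ev$chrom2), states = NULL,
                 shattered_chrom = NULL, config = config),
            class = "sv_plan")
}

plan_chromothripsis <- function(genome, target_chrom, n_events, config,
                                min_segment, keep_prob) {
  lens <- genome_lengths(genome)
  assert_that(target_chrom %in% names(lens), "unknown target chromosome.")
  L <- lens[[target_chrom]]
  n_seg <- 2L * n_events
  if (L < 1.5 * n_seg * min_segment) {
    abort("chromosome too short for requested events.")
  }
  # broken-stick segment lengths: min_segment guaranteed, remainder
  # spread by uniform spacings
  slack <- L - n_seg * min_segment
  u <- sort(runif(n_seg - 1L, 0, slack))
  gaps <- diff(c(0, u, slack)) + min_segment
  cuts <- as.integer(round(cumsum(gaps)[-n_seg]))
  frag <- tibble(start = c(1L, cuts + 1L), end = c(cuts, L))
  repeat {
    keep <- rbinom(n_seg, 1, keep_prob) == 1
    if (sum(keep) >= 2 && sum(!keep) >= 1) break
  }
  kept <- frag[keep, ]
  ord <- sample(nrow(kept))
  assembly <- kept[ord, ] |>
    mutate(der_chrom = paste0("der_", target_chrom),
           seg_order = row_number(),
           chrom = target_chrom,
           orient = sample(c("+", "-"), dplyr::n(), replace = TRUE)) |>
    select("der_chrom", "seg_order", "chrom", "start", "end", "orient")
  # fragments that happen to be reassembled in native order and
  # orientation are one contiguous piece, not a junction: merge them
  assembly <- merge_collinear_segments(assembly)
  nj <- nrow(assembly) - 1L
  specs <- draw_junction_specs(nj, config)
  junctions <- bind_cols(tibble(after_seg = seq_len(nj),
                                event_id = "chromothripsis"), specs) |>
    mutate(der_chrom = paste0("der_", target_chrom),
           junction_id = sprintf("%s_j%d", .data$der_chrom, row_number())) |>
    finalize_junction_details(assembly, genome, config)
  # true copy states when one intact homolog is retained alongside
  states <- frag |>
    mutate(chrom = target_chrom, state = ifelse(keep, 2L, 1L)) |>
    select("chrom", "start", "end", "state")
  states <- merge_equal_states(states)
  structure(list(mode = "chromothripsis", events = NULL, assembly = assembly,
                 junctions = junctions, replaced = target_chrom,
                 states = states, shattered_chrom = target_chrom,
                 config = config),
            class = "sv_plan")
}

merge_collinear_segments <- function(assembly) {
  out <- assembly[1, ]
  for (i in seq_len(nrow(assembly))[-1]) {
    prev <- out[nrow(out), ]
    cur <- assembly[i, ]
    collinear <- prev$chrom == cur$chrom && prev$orient == cur$orient &&
      ((prev$orient == "+" && cur$start == prev$end + 1L) ||
         (prev$orient == "-" && cur$end == prev$start - 1L))
    if (collinear) {
      out$start[nrow(out)] <- min(prev$start, cur$start)
      out$end[nrow(out)] <- max(prev$end, cur$end)
    } else {
      out <- bind_rows(out, cur)
    }
  }
  out$seg_order <- seq_len(nrow(out))
  out
}

merge_equal_states <- function(states) {
  states |>
    group_by(.data$chrom) |>
    mutate(grp = cumsum(c(1L, diff(.data$state) != 0))) |>
    group_by(.data$chrom, .data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              state = .data$state[1], .groups = "drop") |>
    select("chrom", "start", "end", "state") |>
    arrange(.data$chrom, .data$start)
}

#' @export
print.sv_plan <- function(x, ...) {
  cat("<sv_plan> mode =", x$mode, "|", nrow(x$assembly), "segments,",
      nrow(x$junctions), "junctions; replaces:",
      paste(x$replaced, collapse = ", "), "\n")
  invisible(x)
}
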