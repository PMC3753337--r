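# Rendering of derived (rearranged) genomes.
#
# Junction engineering happens on the reference *before* any sequence is
# extracted, so the reference and the derived chromosome stay consistent:
#  * microhomology m is planted by overwriting the first m bases of the
#    acceptor segment in the reference with the donor segment's
#    continuation, so both partners share the m-base word at the join;
#  * one base at each slide boundary is adjusted ("blocked") where needed
#    so the realised microhomology equals the planted length exactly;
#  * untemplated insertions have their terminal bases adjusted so they
#    cannot be absorbed into either flank alignment;
#  * shard/templated fragments are copied verbatim and all four fragment
#    boundaries are blocked.
# A lock set guards every base that participates in a planted constraint;
# overlapping constraints raise a "junction spec conflicts" error.

seg_pos <- function(seg, which, j) {
  # donor-frame positions around a segment's derived ends
  switch(which,
    last = if (seg$orient == "+") seg$end - (j - 1L) else seg$start + (j - 1L),
    cont = if (seg$orient == "+") seg$end + j else seg$start - j,
    first = if (seg$orient == "+") seg$start + (j - 1L) else seg$end - (j - 1L),
    pre = if (seg$orient == "+") seg$start - j else seg$end + j
  )
}

new_render_state <- function(genome) {
  env <- new.env(parent = emptyenv())
  env$chrs <- as.list(setNames(as.character(genome$seqs), names(genome$seqs)))
  env$locked <- lapply(env$chrs, function(...) integer(0))
  env
}

rs_value <- function(st, chrom, pos, orient) {
  b <- substr(st$chrs[[chrom]], pos, pos)
  if (orient == "-") complement_base(b) else b
}

rs_locked <- function(st, chrom, pos) pos %in% st$locked[[chrom]]

rs_lock <- function(st, chrom, pos) {
  st$locked[[chrom]] <- c(st$locked[[chrom]], pos)
}

# Write a derived-frame value; returns FALSE (without writing) when the
# position is locked by an earlier constraint.
rs_write <- function(st, chrom, pos, value, orient) {
  if (rs_locked(st, chrom, pos)) return(FALSE)
  b <- if (orient == "-") complement_base(value) else value
  substr(st$chrs[[chrom]], pos, pos) <- b
  rs_lock(st, chrom, pos)
  TRUE
}

in_bounds <- function(st, chrom, pos) {
  pos >= 1 && pos <= nchar(st$chrs[[chrom]])
}

# Make derived-frame values at two positions differ, mutating whichever
# side is not locked (preference to side1); locks both. When both sides
# are already locked the chance match stands and is picked up by the
# realised-state truth measurement.
ensure_diff <- function(st, c1, p1, o1, c2, p2, o2) {
  if (!in_bounds(st, c1, p1) || !in_bounds(st, c2, p2)) return(invisible())
  v1 <- rs_value(st, c1, p1, o1)
  v2 <- rs_value(st, c2, p2, o2)
  if (v1 == v2) {
    if (!rs_locked(st, c1, p1)) {
      rs_write(st, c1, p1, other_base(v2), o1)
      rs_lock(st, c2, p2)
    } else if (!rs_locked(st, c2, p2)) {
      rs_write(st, c2, p2, other_base(v1), o2)
      rs_lock(st, c1, p1)
    }
  } else {
    rs_lock(st, c1, p1)
    rs_lock(st, c2, p2)
  }
  invisible()
}

rs_frame_value <- function(st, chrom, pos, orient) {
  if (!in_bounds(st, chrom, pos)) return(NA_character_)
  rs_value(st, chrom, pos, orient)
}

# Realised slide extensions at a junction in the final reference state:
# u = left extension (segL terminal bases reappearing before segR's
# donor start), v = right extension (segL continuation reappearing at
# segR's donor start). Realised microhomology = u + v.
realized_ext <- function(st, segL, segR, max_ext = 60L) {
  u <- 0L
  while (u < max_ext) {
    a <- rs_frame_value(st, segL$chrom, seg_pos(segL, "last", u + 1L),
                        segL$orient)
    b <- rs_frame_value(st, segR$chrom, seg_pos(segR, "pre", u + 1L),
                        segR$orient)
    if (is.na(a) || is.na(b) || a != b) break
    u <- u + 1L
  }
  v <- 0L
  while (v < max_ext) {
    a <- rs_frame_value(st, segL$chrom, seg_pos(segL, "cont", v + 1L),
                        segL$orient)
    b <- rs_frame_value(st, segR$chrom, seg_pos(segR, "first", v + 1L),
                        segR$orient)
    if (is.na(a) || is.na(b) || a != b) break
    v <- v + 1L
  }
  list(u = u, v = v)
}

plant_junction <- function(st, segL, segR, jrow) {
  a <- function(which, j) seg_pos(segL, which, j)
  b <- function(which, j) seg_pos(segR, which, j)
  type <- jrow$type
  ins_seq <- jrow$ins_seq %|NA|% ""
  if (type %in% c("microhomology", "blunt")) {
    m <- jrow$mh_len
    if (m > 0) {
      for (j in seq_len(m)) {
        src_pos <- a("cont", j)
        tgt_pos <- b("first", j)
        if (!in_bounds(st, segL$chrom, src_pos)) break
        v <- rs_value(st, segL$chrom, src_pos, segL$orient)
        if (!rs_write(st, segR$chrom, tgt_pos, v, segR$orient)) break
        rs_lock(st, segL$chrom, src_pos)
      }
    }
    ensure_diff(st, segL$chrom, a("cont", m + 1L), segL$orient,
                segR$chrom, b("first", m + 1L), segR$orient)
    ensure_diff(st, segR$chrom, b("pre", 1L), segR$orient,
                segL$chrom, a("last", 1L), segL$orient)
    ins_seq <- ""
  } else if (type == "insertion") {
    v_a <- rs_value(st, segL$chrom, a("cont", 1L), segL$orient)
    v_b <- rs_value(st, segR$chrom, b("pre", 1L), segR$orient)
    n <- nchar(ins_seq)
    if (n == 1L) {
      if (substr(ins_seq, 1, 1) %in% c(v_a, v_b)) {
        ins_seq <- other_base(c(v_a, v_b))
      }
    } else {
      if (substr(ins_seq, 1, 1) == v_a) {
        substr(ins_seq, 1, 1) <- other_base(v_a)
      }
      if (substr(ins_seq, n, n) == v_b) {
        substr(ins_seq, n, n) <- other_base(v_b)
      }
    }
    rs_lock(st, segL$chrom, a("cont", 1L))
    rs_lock(st, segR$chrom, b("pre", 1L))
  } else { # shard / templated
    fr <- list(chrom = jrow$frag_chrom, start = jrow$frag_start,
               end = jrow$frag_end, orient = jrow$frag_orient)
    f <- function(which, j) seg_pos(fr, which, j)
    ensure_diff(st, segL$chrom, a("cont", 1L), segL$orient,
                fr$chrom, f("first", 1L), fr$orient)
    ensure_diff(st, fr$chrom, f("pre", 1L), fr$orient,
                segL$chrom, a("last", 1L), segL$orient)
    ensure_diff(st, fr$chrom, f("cont", 1L), fr$orient,
                segR$chrom, b("first", 1L), segR$orient)
    ensure_diff(st, segR$chrom, b("pre", 1L), segR$orient,
                fr$chrom, f("last", 1L), fr$orient)
  }
  ins_seq
}

#' Render a derived genome from rearrangement plans
#'
#' Applies one or more rearrangement plans to a genome: plants the
#' specified junction structure (microhomology, blunt join, untemplated
#' insertion, genomic shard or templated insertion of nearby sequence)
#' into the reference, assembles the derivative chromosome sequences, and
#' records the exact ground truth for every junction.
#'
#' @param genome An `sv_genome`.
#' @param plans An `sv_plan` or a list of them (see
#'   [plan_rearrangements()]).
#' @param flank Flank length (bp) kept around each junction in the
#'   ground-truth junction-region sequence.
#' @return An object of class `sv_derived` with elements:
#'   * `reference`: the (junction-engineered) reference `sv_genome` that
#'     downstream junction resolution should align against;
#'   * `derived`: an `sv_genome` holding the derivative chromosomes plus
#'     all untouched chromosomes;
#'   * `map`: tibble mapping derived coordinates back to the reference
#'     (`der_chrom`, `der_start`, `der_end`, `chrom`, `start`, `end`,
#'     `orient`; `chrom` is `NA` for untemplated insertions);
#'   * `truth`: ground-truth junction table (`junction_id`, donor
#'     coordinates and strands of both partners, `class`, `mh_len`,
#'     `insertion_seq`, fragment fields, and the junction-region
#'     sequence `region_seq`);
#'   * `states`: true integer copy states per reference interval under a
#'     diploid rendering (chromothripsis plans only).
#' @export
render_derived_genome <- function(genome, plans, flank = 150L) {
  if (inherits(plans, "sv_plan")) plans <- list(plans)
  st <- new_render_state(genome)
  # 1. plant all junctions (mutates the working reference)
  final_ins <- list()
  for (p in plans) {
    asm <- p$assembly
    for (k in seq_len(nrow(p$junctions))) {
      j <- p$junctions[k, ]
      segL <- as.list(asm[j$after_seg, ])
      segR <- as.list(asm[j$after_seg + 1L, ])
      final_ins[[j$junction_id]] <- plant_junction(st, segL, segR, j)
    }
  }
  reference <- new_sv_genome(Biostrings::DNAStringSet(unlist(st$chrs)))
  # 2. assemble derivative chromosomes and ground truth
  map <- list()
  truth <- list()
  der_seqs <- character(0)
  for (p in plans) {
    asm <- p$assembly
    jn <- p$junctions
    der <- asm$der_chrom[1]
    pieces <- list()
    for (i in seq_len(nrow(asm))) {
      s <- as.list(asm[i, ])
      pieces[[length(pieces) + 1]] <- list(
        kind = "segment", chrom = s$chrom, start = s$start, end = s$end,
        orient = s$orient,
        seq = genome_seq(reference, s$chrom, s$start, s$end, s$orient)
      )
      jrow <- jn[jn$after_seg == i, ]
      if (nrow(jrow) == 1) {
        if (jrow$type == "insertion") {
          pieces[[length(pieces) + 1]] <- list(
            kind = "insertion", chrom = NA_character_, start = NA_integer_,
            end = NA_integer_, orient = "+",
            seq = final_ins[[jrow$junction_id]]
          )
        } else if (jrow$type %in% c("shard", "templated")) {
          pieces[[length(pieces) + 1]] <- list(
            kind = "fragment", chrom = jrow$frag_chrom,
            start = jrow$frag_start, end = jrow$frag_end,
            orient = jrow$frag_orient,
            seq = genome_seq(reference, jrow$frag_chrom, jrow$frag_start,
                             jrow$frag_end, jrow$frag_orient)
          )
        }
      }
    }
    lens_p <- vapply(pieces, function(x) nchar(x$seq), integer(1))
    der_end <- cumsum(lens_p)
    der_start <- der_end - lens_p + 1L
    der_seq <- paste(vapply(pieces, `[[`, character(1), "seq"), collapse = "")
    der_seqs[der] <- der_seq
    map[[der]] <- tibble(
      der_chrom = der,
      der_start = der_start, der_end = der_end,
      chrom = vapply(pieces, `[[`, character(1), "chrom"),
      start = vapply(pieces, function(x) x$start %||% NA_integer_, integer(1)),
      end = vapply(pieces, function(x) x$end %||% NA_integer_, integer(1)),
      orient = vapply(pieces, `[[`, character(1), "orient")
    )
    # piece index of each assembly segment within `pieces`
    seg_piece <- which(vapply(pieces, `[[`, character(1), "kind") == "segment")
    truth[[der]] <- purrr::map_dfr(seq_len(nrow(jn)), function(k) {
      j <- as.list(jn[k, ])
      segL <- as.list(asm[j$after_seg, ])
      segR <- as.list(asm[j$after_seg + 1L, ])
      ins <- final_ins[[j$junction_id]]
      cls <- j$type
      m <- 0L
      m2 <- NA_integer_
      pos_a <- seg_pos(segL, "last", 1L)
      pos_b <- seg_pos(segR, "first", 1L)
      gap_len <- 0L
      frag_dist <- NA_real_
      if (j$type %in% c("microhomology", "blunt")) {
        # realised slide length in the final reference (equals the planted
        # length whenever both boundary blocks could be applied)
        ext <- realized_ext(st, segL, segR)
        m <- ext$u + ext$v
        cls <- if (m >= 1) "microhomology" else "blunt"
        if (ext$v > 0) pos_a <- seg_pos(segL, "cont", ext$v)
        if (ext$u > 0) pos_b <- seg_pos(segR, "pre", ext$u)
      } else if (j$type == "insertion") {
        gap_len <- nchar(ins)
      } else {
        fr <- list(chrom = j$frag_chrom, start = j$frag_start,
                   end = j$frag_end, orient = j$frag_orient)
        ext1 <- realized_ext(st, segL, fr)
        ext2 <- realized_ext(st, fr, segR)
        m <- ext1$u + ext1$v
        m2 <- ext2$u + ext2$v
        if (ext1$v > 0) pos_a <- seg_pos(segL, "cont", ext1$v)
        if (ext2$u > 0) pos_b <- seg_pos(segR, "pre", ext2$u)
        gap_len <- j$frag_end - j$frag_start + 1L
        frag_dist <- frag_distance(j, segL$chrom, pos_a, segR$chrom, pos_b)
      }
      dpos <- der_end[seg_piece[j$after_seg]]
      r_start <- max(1L, dpos - flank + 1L)
      r_end <- min(nchar(der_seq), dpos + gap_len + flank)
      tibble(
        junction_id = j$junction_id, der_chrom = der, der_pos = dpos,
        chromA = segL$chrom, posA = pos_a, strandA = segL$orient,
        chromB = segR$chrom, posB = pos_b, strandB = segR$orient,
        class = cls, mh_len = m, mh_len2 = m2,
        insertion_seq = if (j$type == "insertion") ins else "",
        frag_chrom = j$frag_chrom %||% NA_character_,
        frag_start = j$frag_start %||% NA_integer_,
        frag_end = j$frag_end %||% NA_integer_,
        frag_strand = j$frag_orient %||% NA_character_,
        frag_distance = frag_dist,
        event_id = j$event_id,
        region_seq = substr(der_seq, r_start, r_end)
      )
    })
  }
  replaced <- unique(unlist(lapply(plans, `[[`, "replaced")))
  untouched <- setdiff(names(genome$seqs), replaced)
  all_seqs <- c(der_seqs,
                setNames(as.character(reference$seqs[untouched]), untouched))
  id_map <- purrr::map_dfr(untouched, function(ch) {
    tibble(der_chrom = ch, der_start = 1L,
           der_end = nchar(all_seqs[[ch]]), chrom = ch, start = 1L,
           end = nchar(all_seqs[[ch]]), orient = "+")
  })
  states <- bind_rows(purrr::compact(lapply(plans, `[[`, "states")))
  structure(
    list(reference = reference,
         derived = new_sv_genome(Biostrings::DNAStringSet(all_seqs)),
         map = bind_rows(c(map, list(id_map))),
         truth = bind_rows(truth),
         states = if (nrow(states)) states else NULL,
         plans = plans,
         replaced = replaced),
    class = "sv_derived"
  )
}

frag_distance <- function(j, chromA, posA, chromB, posB) {
  d <- Inf
  if (identical(j$frag_chrom, chromA)) {
    d <- min(d, min(abs(c(j$frag_start, j$frag_end) - posA)))
  }
  if (identical(j$frag_chrom, chromB)) {
    d <- min(d, min(abs(c(j$frag_start, j$frag_end) - posB)))
  }
  d
}

#' @export
print.sv_derived <- function(x, ...) {
  cat("<sv_derived> ", length(x$derived$seqs), " sequence(s), ",
      nrow(x$truth), " true junction(s)\n", sep = "")
  invisible(x)
}
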