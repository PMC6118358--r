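#' DNA strands and strand-displacement gates
#'
#' A strand-displacement gate is a protector/template duplex engineered with
#' an exposed single-stranded toehold, plus the invader strand that removes
#' the dye-labeled template by toehold-mediated branch migration. `strand()`
#' builds one validated strand; `gate_set()` assembles the three strands of a
#' gate and derives its duplex and toehold structure.
#'
#' Sequences are stored 5'-to-3' over the DNA alphabet `A/C/G/T`,
#' case-insensitive on input and canonicalized to upper case (`U` is
#' rejected). A `linker` is a short non-hybridizing 3' extension (for the
#' gates shipped with the package, the `TT` spacer preceding the 3' azide on
#' each protector); it is excluded from every complementarity computation.
#'
#' @param sequence DNA sequence, 5'-to-3'.
#' @param role One of `"protector"`, `"template"`, `"invader"`.
#' @param name Strand name; defaults to the role.
#' @param five_prime_mod,three_prime_mod Optional terminal modification
#'   labels (e.g. `"5Alex647N"`, `"3AzideN"`); stored, never interpreted.
#' @param linker Optional non-hybridizing 3' linker sequence.
#' @return `strand()` returns a `seqstorm_strand` object: a list with fields
#'   `name`, `role`, `sequence`, `five_prime_mod`, `three_prime_mod`,
#'   `linker`.
#' @examples
#' p <- strand("GCCTGCTTTATCTCTGTTCTACTATTTCCG", "protector", linker = "TT")
#' nchar(hybridizing_sequence(p))
#' @export
strand <- function(sequence, role = c("protector", "template", "invader"),
                   name = NULL, five_prime_mod = NULL, three_prime_mod = NULL,
                   linker = NULL) {
  role <- match.arg(role)
  sequence <- canonicalize_dna(sequence)
  if (!is.null(linker)) {
    linker <- canonicalize_dna(linker)
  }
  structure(
    list(
      name = name %||% role,
      role = role,
      sequence = sequence,
      five_prime_mod = five_prime_mod,
      three_prime_mod = three_prime_mod,
      linker = linker
    ),
    class = "seqstorm_strand"
  )
}

#' @export
print.seqstorm_strand <- function(x, ...) {
  mods <- c(
    if (!is.null(x$five_prime_mod)) paste0("/", x$five_prime_mod, "/"),
    x$sequence,
    if (!is.null(x$linker)) tolower(x$linker),
    if (!is.null(x$three_prime_mod)) paste0("/", x$three_prime_mod, "/")
  )
  cat(sprintf("<strand %s (%s), %d nt> 5'-%s-3'\n",
              x$name, x$role, nchar(x$sequence), paste(mods, collapse = "")))
  invisible(x)
}

# upper-case, validate alphabet; errors name the first offending position
canonicalize_dna <- function(sequence, arg = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    abort(sprintf("`%s` must be a single string.", arg),
          class = "seqstorm_invalid_alphabet")
  }
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad) > 0L) {
    abort(
      sprintf(
        "`%s` contains non-ACGT character '%s' at position %d%s.",
        arg, chars[bad[1L]], bad[1L],
        if (chars[bad[1L]] == "U") " (RNA not supported)" else ""
      ),
      class = "seqstorm_invalid_alphabet"
    )
  }
  if (nchar(sequence) < 1L) {
    abort(sprintf("`%s` must have length >= 1.", arg),
          class = "seqstorm_invalid_alphabet")
  }
  sequence
}

#' @rdname strand
#' @param x A `seqstorm_strand`.
#' @return `hybridizing_sequence()` returns the strand sequence with any
#'   3' linker removed — the part that participates in base pairing.
#' @export
hybridizing_sequence <- function(x) {
  stopifnot(inherits(x, "seqstorm_strand"))
  x$sequence
}

#' Antiparallel Watson-Crick reverse complement
#'
#' Strict Watson-Crick pairing (A-T, G-C, no wobble). Applying the function
#' twice returns the input.
#'
#' @param sequence DNA string (or character vector of strings), 5'-to-3'.
#' @return The reverse complement(s), 5'-to-3'.
#' @examples
#' reverse_complement("GCCTGCTTTATCTCTGTTCTACTATTTCCG")
#' @export
reverse_complement <- function(sequence) {
  vapply(sequence, function(s) {
    s <- canonicalize_dna(s)
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                                 collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

as_hyb_chars <- function(x, arg) {
  s <- if (inherits(x, "seqstorm_strand")) hybridizing_sequence(x) else
    canonicalize_dna(x, arg)
  strsplit(s, "", fixed = TRUE)[[1L]]
}

WC_PARTNER <- c(A = "T", C = "G", G = "C", T = "A")

#' Maximal ungapped antiparallel duplex between two strands
#'
#' Slides strand `b` (reversed, i.e. antiparallel) along strand `a` over all
#' relative offsets and returns the offset with the most Watson-Crick paired
#' positions. Linkers are excluded. Ties are broken by the smallest absolute
#' offset, then by the 5'-most aligned start on `a`, so the result is
#' deterministic.
#'
#' @param a,b `seqstorm_strand` objects or plain DNA strings.
#' @return A list with `paired_count` (number of Watson-Crick pairs at the
#'   best offset), `offset` (the winning relative offset), and `alignment`, a
#'   tibble with one row per overlapping position: 1-based `pos_a`, `pos_b`,
#'   the two bases, and whether they `pair`.
#' @examples
#' duplex_map("ACGTACGT", reverse_complement("ACGTACGT"))$paired_count
#' @export
duplex_map <- function(a, b) {
  ca <- as_hyb_chars(a, "a")
  cb <- as_hyb_chars(b, "b")
  na <- length(ca)
  nb <- length(cb)
  # antiparallel: reverse b once; pos k of rb is pos nb - k + 1 of b
  rb <- rev(cb)
  need <- unname(WC_PARTNER[ca])
  # offset d: a[i] aligned with rb[i - d], d in [-(nb-1), na-1]
  offsets <- seq.int(-(nb - 1L), na - 1L)
  counts <- vapply(offsets, function(d) {
    i <- seq.int(max(1L, 1L + d), min(na, nb + d))
    sum(need[i] == rb[i - d])
  }, integer(1))
  best <- max(counts)
  cand <- offsets[counts == best]
  d <- cand[order(abs(cand), cand)][1L]
  i <- seq.int(max(1L, 1L + d), min(na, nb + d))
  j <- i - d                      # index into rb
  alignment <- tibble::tibble(
    pos_a = i,
    pos_b = nb - j + 1L,
    base_a = ca[i],
    base_b = cb[nb - j + 1L],
    pair = need[i] == rb[j]
  )
  list(paired_count = as.integer(best), offset = as.integer(d),
       alignment = alignment)
}

#' Assemble and interrogate a strand-displacement gate
#'
#' `gate_set()` bundles a protector, template and invader strand and derives
#' the duplex length (Watson-Crick pairs between template and protector) and
#' the toehold (the contiguous single-stranded template region the protector
#' leaves unpaired, where the invader nucleates).
#'
#' @param name Gate set name, e.g. `"A"`.
#' @param protector,template,invader `seqstorm_strand` objects or plain DNA
#'   strings (coerced with the matching role).
#' @return A `seqstorm_gate` list with the three strands, `duplex_length`,
#'   and `toehold` (see [toehold_of()]).
#' @examples
#' gates <- printed_gate_sets()
#' gates$A$duplex_length
#' gates$A$toehold$segment_sequence
#' @export
gate_set <- function(name, protector, template, invader) {
  coerce <- function(x, role) {
    if (inherits(x, "seqstorm_strand")) x else strand(x, role)
  }
  gate <- structure(
    list(
      name = name,
      protector = coerce(protector, "protector"),
      template = coerce(template, "template"),
      invader = coerce(invader, "invader")
    ),
    class = "seqstorm_gate"
  )
  gate$duplex_length <- duplex_map(gate$template, gate$protector)$paired_count
  gate$toehold <- toehold_of(gate)
  gate
}

#' @export
print.seqstorm_gate <- function(x, ...) {
  cat(sprintf(
    "<gate set %s> template %d nt = %d bp duplex + %d nt toehold (%s)\n",
    x$name, nchar(x$template$sequence), x$duplex_length,
    x$toehold$length, x$toehold$segment_sequence))
  invisible(x)
}

#' Toehold of a gate
#'
#' The toehold is the contiguous template segment left single-stranded by the
#' protector; it is where the invader nucleates before branch migration. A
#' template that is fully paired by its protector has no toehold and cannot
#' support toehold-mediated displacement, which is an error.
#'
#' @param gate A `seqstorm_gate`.
#' @return A duplex-segment list: `strand_name`, 0-based half-open `start`
#'   and `end` on the template, `length`, and `segment_sequence`.
#' @export
toehold_of <- function(gate) {
  stopifnot(inherits(gate, "seqstorm_gate"))
  dm <- duplex_map(gate$template, gate$protector)
  tl <- nchar(hybridizing_sequence(gate$template))
  paired <- dm$alignment$pos_a[dm$alignment$pair]
  unpaired <- setdiff(seq_len(tl), paired)
  if (length(unpaired) == 0L) {
    abort(
      sprintf("gate %s: template is fully paired by the protector (no toehold).",
              gate$name),
      class = "seqstorm_zero_toehold"
    )
  }
  # longest contiguous unpaired run (1-based positions)
  runs <- split(unpaired, cumsum(c(1L, diff(unpaired) != 1L)))
  seg <- runs[[which.max(lengths(runs))]]
  start0 <- seg[1L] - 1L
  end0 <- seg[length(seg)]
  list(
    strand_name = gate$template$name,
    start = start0,
    end = end0,
    length = end0 - start0,
    segment_sequence = substr(hybridizing_sequence(gate$template),
                              start0 + 1L, end0)
  )
}

#' Structural validation of a gate
#'
#' Runs the named structural checks a working toehold-exchange gate must
#' satisfy: the protector's hybridizing region is fully paired, the duplex is
#' one contiguous block, duplex plus toehold tile the template, the toehold
#' is non-empty, the invader is the full-length reverse complement of the
#' template, and the invader's 5' end complements the toehold (so a
#' nucleation region exists). Failures are rows of the report, never errors.
#'
#' @param gate A `seqstorm_gate`.
#' @return A tibble (class `gate_validation`) with columns `check`, `value`,
#'   `pass`, `message`.
#' @examples
#' verify_gate(printed_gate_sets()$A)
#' @export
verify_gate <- function(gate) {
  stopifnot(inherits(gate, "seqstorm_gate"))
  tl <- nchar(hybridizing_sequence(gate$template))
  pl <- nchar(hybridizing_sequence(gate$protector))
  il <- nchar(hybridizing_sequence(gate$invader))
  dm_tp <- duplex_map(gate$template, gate$protector)
  toe <- tryCatch(toehold_of(gate), seqstorm_zero_toehold = function(e) NULL)
  toe_len <- if (is.null(toe)) 0L else toe$length
  dm_it <- duplex_map(gate$invader, gate$template)
  paired_t <- sort(dm_tp$alignment$pos_a[dm_tp$alignment$pair])
  duplex_contiguous <- length(paired_t) > 0L && all(diff(paired_t) == 1L)
  nucleation <- if (is.null(toe)) FALSE else {
    substr(hybridizing_sequence(gate$invader), 1L, toe$length) ==
      reverse_complement(toe$segment_sequence)
  }

  checks <- tibble::tibble(
    check = c("template_length", "protector_hybridizing", "duplex_length",
              "toehold_present", "invader_full_complement",
              "invader_toehold_nucleation"),
    value = c(tl, pl, dm_tp$paired_count, toe_len, dm_it$paired_count,
              as.integer(nucleation) * toe_len),
    pass = c(
      tl == dm_tp$paired_count + toe_len,
      dm_tp$paired_count == pl,
      duplex_contiguous && dm_tp$paired_count > 0L,
      toe_len > 0L,
      dm_it$paired_count == tl && il == tl,
      nucleation
    ),
    message = c(
      sprintf("template %d nt = %d bp duplex + %d nt toehold",
              tl, dm_tp$paired_count, toe_len),
      sprintf("protector hybridizing region %d nt, %d paired",
              pl, dm_tp$paired_count),
      sprintf("duplex %d bp, %scontiguous", dm_tp$paired_count,
              if (duplex_contiguous) "" else "NOT "),
      sprintf("toehold %d nt", toe_len),
      sprintf("invader pairs %d of %d template positions",
              dm_it$paired_count, tl),
      if (nucleation) "invader 5' end complements the toehold"
      else "invader 5' end does NOT complement the toehold"
    )
  )
  class(checks) <- c("gate_validation", class(checks))
  attr(checks, "gate") <- gate$name
  checks
}

# longest ungapped antiparallel WC run between two strands, over all offsets
longest_complementary_run <- function(a, b) {
  ca <- as_hyb_chars(a, "a")
  cb <- as_hyb_chars(b, "b")
  na <- length(ca)
  nb <- length(cb)
  rb <- rev(cb)
  need <- unname(WC_PARTNER[ca])
  best <- 0L
  best_a <- NA_integer_
  best_b <- NA_integer_
  for (d in seq.int(-(nb - 1L), na - 1L)) {
    i <- seq.int(max(1L, 1L + d), min(na, nb + d))
    m <- need[i] == rb[i - d]
    if (!any(m)) next
    r <- rle(m)
    ends <- cumsum(r$lengths)
    runs_true <- which(r$values)
    len <- max(r$lengths[runs_true])
    if (len > best) {
      best <- len
      k <- runs_true[which.max(r$lengths[runs_true])]
      a_start <- i[ends[k] - r$lengths[k] + 1L]
      best_a <- a_start
      best_b <- nb - (a_start - d) + 1L  # 1-based pos on b of the run start
    }
  }
  list(longest_run = best, a_start = best_a, b_start = best_b)
}

#' Cross-set orthogonality screen
#'
#' For every inter-set strand pair (3 x 3 = 9 pairs), computes the longest
#' ungapped antiparallel Watson-Crick complementary run over all alignment
#' offsets. Two sets are classified orthogonal when the maximum run over all
#' pairs falls below `threshold` consecutive complementary bases. The
#' run-length score is an explicit operational stand-in for a thermodynamic
#' orthogonality criterion; the threshold is always reported, never silent.
#'
#' @param set_a,set_b `seqstorm_gate` objects.
#' @param threshold Runs of at least this many consecutive complementary
#'   bases flag a potential cross-interaction (default 10).
#' @return A `crossreactivity_report`: list with `set_a`, `set_b`,
#'   `per_pair_scores` (tibble: strand names, `longest_complementary_run`,
#'   1-based run start on each strand), `max_run`, `threshold`, `orthogonal`,
#'   and `intra_set` (TRUE, with a warning flag, when a set is screened
#'   against itself — intra-set strands are complementary by design).
#' @examples
#' g <- printed_gate_sets()
#' cross_reactivity(g$A, g$B)$max_run
#' @export
cross_reactivity <- function(set_a, set_b, threshold = 10) {
  stopifnot(inherits(set_a, "seqstorm_gate"), inherits(set_b, "seqstorm_gate"))
  intra <- identical(set_a$name, set_b$name)
  roles <- c("protector", "template", "invader")
  per_pair <- purrr::map_dfr(roles, function(ra) {
    purrr::map_dfr(roles, function(rb) {
      run <- longest_complementary_run(set_a[[ra]], set_b[[rb]])
      tibble::tibble(
        strand_a = paste0(set_a$name, "_", ra),
        strand_b = paste0(set_b$name, "_", rb),
        longest_complementary_run = run$longest_run,
        a_start = run$a_start,
        b_start = run$b_start
      )
    })
  })
  max_run <- max(per_pair$longest_complementary_run)
  structure(
    list(
      set_a = set_a$name,
      set_b = set_b$name,
      per_pair_scores = per_pair,
      max_run = as.integer(max_run),
      threshold = threshold,
      orthogonal = max_run < threshold,
      intra_set = intra
    ),
    class = "crossreactivity_report"
  )
}

#' @export
print.crossreactivity_report <- function(x, ...) {
  cat(sprintf(
    "<cross-reactivity %s vs %s> max complementary run %d nt (threshold %g): %s\n",
    x$set_a, x$set_b, x$max_run, x$threshold,
    if (x$orthogonal) "orthogonal" else "NOT orthogonal"))
  if (x$intra_set)
    cat("  note: intra-set comparison; strands are complementary by design\n")
  invisible(x)
}

#' Read gate sets from a FASTA-like file
#'
#' Records are named `>SET_ROLE` (e.g. `>A_protector`). Sequence lines may
#' carry IDT-style modification tokens (`/5Alex647N/`, `/3AzideN/`), which
#' are stripped and stored as modification fields, and lower-case bases,
#' which mark a non-hybridizing 3' linker (e.g. the `TT` spacer before a 3'
#' azide). Whitespace inside sequences is ignored.
#'
#' @param path Path to the gate file.
#' @return A named list of `seqstorm_gate` objects, one per set.
#' @export
read_gates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) abort("no '>' records found in gate file.")
  records <- purrr::map2(hdr, c(hdr[-1L] - 1L, length(lines)), function(h, e) {
    name <- sub("^>\\s*", "", lines[h])
    seq <- paste(lines[seq.int(h + 1L, e)], collapse = "")
    seq <- gsub("[[:space:]]", "", seq)
    mods <- regmatches(seq, gregexpr("/[^/]+/", seq))[[1L]]
    five <- sub("^/|/$", "", grep("^/5", mods, value = TRUE))
    three <- sub("^/|/$", "", grep("^/3", mods, value = TRUE))
    three <- gsub("/", "", three)
    five <- gsub("/", "", five)
    seq <- gsub("/[^/]+/", "", seq)
    # lower-case tail = non-hybridizing linker
    linker <- sub("^.*?([acgt]+)$", "\\1", seq)
    if (identical(linker, seq)) linker <- ""
    core <- substr(seq, 1L, nchar(seq) - nchar(linker))
    list(name = name, core = core, linker = linker,
         five = if (length(five)) five[[1L]] else NULL,
         three = if (length(three)) three[[1L]] else NULL)
  })
  parts <- strsplit(vapply(records, `[[`, "", "name"), "_", fixed = TRUE)
  sets <- vapply(parts, `[[`, "", 1L)
  roles <- tolower(vapply(parts, function(p) paste(p[-1L], collapse = "_"), ""))
  bad <- which(!roles %in% c("protector", "template", "invader"))
  if (length(bad) > 0L) {
    abort(sprintf("record '%s': role must be protector/template/invader.",
                  records[[bad[1L]]]$name))
  }
  purrr::map(split(seq_along(records), sets), function(idx) {
    got <- setNames(idx, roles[idx])
    missing <- setdiff(c("protector", "template", "invader"), names(got))
    if (length(missing) > 0L) {
      abort(sprintf("set %s is missing: %s", sets[idx[1L]],
                    paste(missing, collapse = ", ")))
    }
    mk <- function(role) {
      r <- records[[got[[role]]]]
      strand(r$core, role, name = r$name,
             five_prime_mod = r$five, three_prime_mod = r$three,
             linker = if (nzchar(r$linker)) r$linker else NULL)
    }
    gate_set(sets[idx[1L]], mk("protector"), mk("template"), mk("invader"))
  })
}

#' The two published orthogonal gate sets
#'
#' Returns the two orthogonal strand-displacement gate sets (Set A and
#' Set B) shipped with the package: 38-nt templates, 30-nt protector
#' hybridizing regions (plus a TT azide linker), 8-nt toeholds, and
#' full-length 38-nt invaders.
#'
#' @return Named list of two `seqstorm_gate` objects, `A` and `B`.
#' @examples
#' printed_gate_sets()$B
#' @export
printed_gate_sets <- function() {
  read_gates(system.file("extdata", "gates_AB.fasta", package = "seqstorm",
                         mustWork = TRUE))
}
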