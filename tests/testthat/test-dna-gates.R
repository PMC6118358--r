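test_that("reverse_complement is a strict Watson-Crick involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAAA"), "TTTT")
  set.seed(101)
  for (i in 1:1000) {
    s <- random_dna(sample(1:40, 1))
    expect_equal(reverse_complement(reverse_complement(s)), s)
    expect_equal(reverse_complement(s), oracle_revcomp(s))
  }
})

test_that("invalid alphabet errors name the offending position", {
  expect_error(reverse_complement("ACGUX"), "position 4",
               class = "seqstorm_invalid_alphabet")
  expect_error(strand("ACGU", "template"), "RNA",
               class = "seqstorm_invalid_alphabet")
  expect_equal(strand("acgt", "template")$sequence, "ACGT")
})

test_that("the shipped protector is the antiparallel complement of the template 5' region", {
  g <- printed_gate_sets()
  expect_equal(
    reverse_complement(hybridizing_sequence(g$A$protector)),
    substr(g$A$template$sequence, 1, 30)
  )
  expect_equal(
    reverse_complement(hybridizing_sequence(g$B$protector)),
    substr(g$B$template$sequence, 1, 30)
  )
})

test_that("gate file parsing captures modifications and the TT linker", {
  g <- printed_gate_sets()
  expect_equal(g$A$protector$linker, "TT")
  expect_equal(g$A$protector$three_prime_mod, "3AzideN")
  expect_equal(g$A$template$five_prime_mod, "5Alex647N")
  expect_equal(nchar(hybridizing_sequence(g$A$protector)), 30)
  expect_equal(nchar(g$B$template$sequence), 38)
})

test_that("duplex_map finds the stated duplexes and is symmetric", {
  g <- printed_gate_sets()
  expect_equal(duplex_map(g$A$template, g$A$protector)$paired_count, 30L)
  expect_equal(duplex_map(g$B$template, g$B$protector)$paired_count, 30L)
  expect_equal(duplex_map(g$A$invader, g$A$template)$paired_count, 38L)
  expect_equal(duplex_map(g$B$invader, g$B$template)$paired_count, 38L)
  set.seed(11)
  for (i in 1:50) {
    a <- random_dna(sample(5:40, 1))
    b <- random_dna(sample(5:40, 1))
    expect_equal(duplex_map(a, b)$paired_count,
                 duplex_map(b, a)$paired_count)
  }
  # a strand against its own reverse complement pairs fully
  s <- random_dna(25)
  expect_equal(duplex_map(s, reverse_complement(s))$paired_count, 25L)
})

test_that("toeholds are the 3'-terminal 8 nt of each template", {
  g <- printed_gate_sets()
  expect_equal(g$A$toehold$segment_sequence, "AAACGAAA")
  expect_equal(g$B$toehold$segment_sequence, "TTGATATT")
  for (set in g) {
    expect_equal(set$toehold$length, 8L)
    expect_equal(set$toehold$start, 30L)
    expect_equal(set$toehold$end, 38L)
    expect_equal(set$duplex_length + set$toehold$length,
                 nchar(set$template$sequence))
  }
})

test_that("a fully protected template has no toehold and errors", {
  p <- random_dna(30)
  expect_error(
    gate_set("X", p, reverse_complement(p), p),
    class = "seqstorm_zero_toehold"
  )
})

test_that("verify_gate passes both shipped sets and catches a swapped invader", {
  g <- printed_gate_sets()
  for (set in g) {
    rep <- verify_gate(set)
    expect_true(all(rep$pass))
    expect_equal(rep$value[rep$check == "template_length"], 38)
    expect_equal(rep$value[rep$check == "protector_hybridizing"], 30)
    expect_equal(rep$value[rep$check == "duplex_length"], 30)
    expect_equal(rep$value[rep$check == "toehold_present"], 8)
    expect_equal(rep$value[rep$check == "invader_full_complement"], 38)
  }
  # wrong-set invader: full complementarity check must fail
  bad <- gate_set("A", g$A$protector, g$A$template, g$B$invader)
  rep <- verify_gate(bad)
  expect_false(rep$pass[rep$check == "invader_full_complement"])
  expect_false(glance(rep)$all_pass)
})

test_that("cross-set reactivity matches the brute-force oracle and flags intra-set", {
  g <- printed_gate_sets()
  cr <- cross_reactivity(g$A, g$B)
  expect_false(cr$intra_set)
  expect_true(cr$orthogonal)
  # exhaustive substring oracle over all 9 inter-set pairs
  strands_a <- lapply(g$A[c("protector", "template", "invader")],
                      hybridizing_sequence)
  strands_b <- lapply(g$B[c("protector", "template", "invader")],
                      hybridizing_sequence)
  oracle_max <- max(vapply(strands_a, function(a) {
    max(vapply(strands_b, function(b) oracle_longest_run(a, b), integer(1)))
  }, integer(1)))
  expect_equal(cr$max_run, oracle_max)
  expect_equal(nrow(tidy(cr)), 9L)

  aa <- cross_reactivity(g$A, g$A)
  expect_true(aa$intra_set)
  expect_equal(aa$max_run, 38L)

  homo <- cross_reactivity(
    gate_set("P1", "AAAAAAAA", paste(rep("T", 12), collapse = ""),
             paste(rep("A", 12), collapse = "")),
    gate_set("P2", "GGGGGGGG", paste(rep("C", 12), collapse = ""),
             paste(rep("G", 12), collapse = ""))
  )
  expect_equal(homo$max_run, 0L)
  expect_true(homo$orthogonal)
})

test_that("cross_reactivity agrees with the oracle on random short strands", {
  set.seed(21)
  for (i in 1:25) {
    a <- random_dna(sample(8:40, 1))
    b <- random_dna(sample(8:40, 1))
    expect_equal(
      seqstorm:::longest_complementary_run(a, b)$longest_run,
      oracle_longest_run(a, b)
    )
  }
})
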