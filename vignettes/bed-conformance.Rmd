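---
title: "Methods: BED conformance testing with bedcert"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BED conformance testing with bedcert}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedcert)
```

## The model

A BED file is a sequence of data lines, each with 3–12 whitespace-delimited
fields in a fixed order; optional fields form a prefix, so a file has one
*variant* BED*n* (or BED*n*+*m* with *m* trailing custom fields).
Coordinates are 0-based and half-open. A *conforming consumer* accepts a
conforming file silently — zero exit status and no error or warning output —
and rejects a non-conforming one with a non-zero exit status or an
error/warning message. Everything in this package reduces to testing that
predicate: the validator implements it directly, the corpus probes it case
by case, the harness measures it on external tools, and the fuzzer searches
for inputs where two consumers disagree about it.

Two verdict-level conventions matter. First, *warnings count as rejection*:
a tool that prints "Warning: skipped line 3" has noticed the problem, which
is what a conformance test measures. Second, the verdict for a tool run is
a pure function of `(exit status, stdout, stderr, timed out?)` plus the
configured message patterns, so results are reproducible.

## The validator

`validate_line()` applies a closed rule table in field order: chrom
character set (`[A-Za-z0-9._-]`, 1–255 characters), unsigned-decimal
coordinates with `chromStart <= chromEnd`, name length/whitespace, score in
0–1000 inclusive, strand in `+ - .`, thick interval nested inside the main
interval, itemRgb either the literal `0` or an 0–255 triple, and block
bookkeeping (positive `blockCount`, lists of exactly that many entries,
first block at offset 0, ascending non-overlapping blocks whose last block
closes the interval). Every violation is a coded issue
(`NEGATIVE_COORD`, `SCORE_RANGE`, `BLOCK_LIST_LENGTH`, ...; see
`rule_codes()`) addressed to a line and field, so error text never needs
parsing downstream.

Dialect is explicit state, never guessed: `bed_dialect()` pins the
delimiter rule (`flexible` splits on runs of tabs and spaces, which the
specification allows when fields contain no spaces; `tabs` splits on single
tabs, so doubled tabs surface as empty — and therefore missing — fields),
blank-line handling (permitted by the specification, so allowed by
default), and comment skipping (off by default: the base format has no
comment syntax, and tools disagree, so skipping is an opt-in dialect
property rather than silent behavior).

Numerical choices: coordinate *ordering* checks compare decimal digit
strings exactly (length, then lexicographic), so tokens at or beyond
2^63−1 are ordered correctly even though R lacks native 64-bit integers;
block-span arithmetic uses doubles, exact below 2^53 — far beyond any
genome. Zero-length intervals (`chromStart == chromEnd`) are accepted: the
half-open convention gives them a coherent meaning (an insertion point) and
nothing in the field rules forbids them. A file's variant is fixed by its
first data line; a later line with a different field count is a
`MIXED_FIELD_COUNT` error, because a parser must infer one field set per
file. Carriage-return line endings produce a warning, not an error: they
are a style hazard, not a rule violation, and warnings never flip a
report's validity.

## The corpus

The corpus is deterministic, built from three stock records on `chr7` and
`chrX` with all coordinates inside [250000, 260000] — positions that exist
on both chromosomes and scaffolds, so secondary files can match. Eight
*base cases* (a fully valid file plus single-rule deviations: negative
start, inverted coordinates, non-numeric coordinate, illegal chromosome
character, score above 1000, fractional score, illegal strand) are
introduced at the variant where their field first exists and repeated at
every wider variant with neutral valid filler (name = case id, score 500,
strand `+`, thick spanning the interval, itemRgb `0`, one block covering
the interval). Nineteen one-off cases cover whole-file properties
(space-delimited files, blank lines between records, all-dot strands),
boundary structure (zero-length interval, 2- and 13-field lines, mixed
field counts, undecodable bytes) and block pathologies. Single-field
deviations flip exactly one field in one record; whole-file deviations set
every record.

Two labels are forced globally: every case landing on BED10 or BED11 is
expected-fail regardless of content (the specification prohibits those
variants), and each expected-fail case triggers at least one error code, so
the 92 cases jointly cover the entire rule table — both facts are asserted
by tests. The total of 92 cases is fixed; the per-variant breakdown
(12, 6, 8, 9, 9, 8, 10, 8, 8, 14 for BED3–BED12; 15 expected-pass in all)
is this package's own design, recorded in the generated `manifest.tsv`
rather than imported from elsewhere.

One corpus case (`other-empty_name`) is delimiter-sensitive: an empty field
between two tabs only exists under the tabs dialect, since flexible
splitting collapses the run. The manifest therefore carries a per-case
dialect, and the harness substitutes it for an optional `DIALECT`
placeholder in a tool's template. Tools without the placeholder simply run
as themselves — an external tool that only accepts tabs will fail the
space-delimited case, which is precisely the kind of disagreement the
score should expose.

## The harness

`evaluate_tool()` visits the full case × tool grid; a per-case timeout
(default 60 s) classifies as fail, since a conformance verdict must
terminate. Message patterns default to case-insensitive `error`, `warning`,
`exception`, `traceback` and are configuration, not code, because real
tools log problems in heterogeneous ways; patterns match as substrings or
regular expressions anywhere in the captured output. Per-variant scores are
`expected_count / total_count`; `summary_table()` sorts tools ascending by
BED3 performance and then by each later variant, and `format_percentage()`
rounds half-up to one decimal.

## The fuzzer

`instantiate_grammar()` is the meta-grammar: from a seed it samples a
concrete BED grammar — delimiter policy (tab-only or tab+space), blank-line
and comment-line allowance, a variant, and per-field value generators.
`generate_file()` then samples a file from that grammar. Both are
deterministic in their seeds and restore the caller's RNG state.
*Strictly-valid* instances keep every generator inside the specification;
the test suite asserts the resulting soundness property (every generated
file is accepted by the validator under the grammar's own dialect) over a
thousand seeds, which cross-checks generator and validator against each
other — any counterexample is a bug in one of them and surfaces as a red
test. *Possibly-invalid* instances mutate exactly one rule (score range
widened, negative starts, extra strand symbols, inverted coordinates, or a
prohibited 10/11-field variant), so a differential discordance is
attributable to a single known deviation; discordant files are recorded
verbatim for triage. Comment lines use `#` prefixes. Trial counts are
user-set; the package takes no position on how many trials a finding
needs.

The grammar engine is a seeded recursive generator over an internal rule
representation rather than a parser-generator toolchain: the method needs
the grammar's *sampling* side only, and a hand-held generator keeps the
dependency surface at zero while remaining byte-reproducible.

## What the synthetic world does and does not establish

Corpus and mock tools make the whole pipeline hermetic: `mock_tool()`
provides always-pass, always-fail, warning, sleeping and
reject-4-field-lines behaviors, and the package's own CLI serves as a real
external consumer for self-conformance (92/92 by construction — a
regression gate, not evidence about third-party software). Green tests
establish that the machinery measures what it claims on files whose ground
truth is known. They do not establish anything about the conformance of
any real tool, which requires running this harness against that tool; nor
does corpus coverage extend to semantics the rule table does not encode
(assembly-dependent bounds such as `chromEnd` beyond chromosome length,
which the validator deliberately does not check because no assembly is
consulted).

## Known limitations

- BED header/metadata lines and bigBed binary encoding are out of scope.
- The validator checks input acceptance, not output correctness of tools.
- Auxiliary secondary-input fixtures are limited to a mock FASTA and
  chromosome-sizes file; BAM/VCF secondary files must be user-supplied
  through the configuration's `settings` section.
- Environment activation supports a conda-style `conda run -n` prefix when
  a `conda` executable is present; otherwise the label is ignored with a
  notice, keeping the harness testable where no environment manager
  exists.
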