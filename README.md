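# bedcert

Conformance testing for the BED (Browser Extensible Data) genomic interval
format.

## The problem

BED is the lingua franca for genomic intervals: plain-text lines of 3–12
whitespace-delimited fields, where `chrom`, `chromStart` and `chromEnd`
(0-based, half-open) are mandatory and the nine optional fields — `name`,
`score`, `strand`, `thickStart`, `thickEnd`, `itemRgb`, `blockCount`,
`blockSizes`, `blockStarts` — must be used as an ordered prefix. BED3–BED9
and BED12 are the eight standard variants; BED10 and BED11 are prohibited.
Because the format long lacked a formal specification, command-line tools
disagree wildly about edge cases: space delimiters, blank lines, score
ranges, negative coordinates, block bookkeeping. Those disagreements break
pipelines and can silently corrupt results.

`bedcert` is for tool developers, reviewers and repository maintainers who
want to *measure* a BED consumer's conformance rather than guess at it. It
provides:

- a **strict validator** implementing the formal field rules as a closed,
  coded rule table (`validate_file()`, `validate_line()`);
- a deterministic **92-case conformance corpus** of expected-pass and
  expected-fail files across BED3–BED12 (`generate_corpus()`);
- a **harness** that runs any command-line tool over the corpus and scores,
  per variant, the fraction of cases where the tool *behaved as expected* —
  accepted a conforming file silently (exit 0, no error/warning output) or
  rejected a non-conforming one (`evaluate_tool()`, `score_by_variant()`);
- a **grammar-based fuzzer** whose meta-grammar samples concrete BED
  grammars (tab-only vs. tab+space, blank lines, comments, per-field value
  ranges) for differential testing of two consumers (`differential_run()`);
- **badges and summary tables** for documenting conformance
  (`make_badges()`, `summary_table()`).

The central statistic is simple: for tool *t* and variant *v*,

```
score(t, v) = #cases of v where t behaved as expected / #cases of v
```

with a case counting as "behaved as expected" when the classified verdict
(pass iff exit status 0, no timeout, and no error/warning pattern in
captured output) matches the case's expectation label.

## Worked example

Validate a file, then score the package's own validator CLI against the
full corpus (self-conformance):

```r
library(bedcert)

f <- tempfile(fileext = ".bed")
writeLines(c("chr7\t250000\t250150", "chr7\t-5\t250150"), f)
print(validate_file(f))
#> BED validation: /tmp/...bed
#>   variant: BED3 | records: 2 | blank lines: 0
#>   2:2:error: [NEGATIVE_COORD] chromStart '-5' is not an unsigned integer
#>   INVALID

corpus <- file.path(tempdir(), "corpus")
generate_corpus(corpus)
results <- evaluate_tool(validator_tool_spec(), corpus)
sum(results$behaved_as_expected)
#> [1] 92
score_by_variant(results)
#>    variant expected_count total_count proportion
#> 1        3             12          12          1
#> 2        4              6           6          1
#> ...                                  (all 10 variants at proportion 1.0)
```

A tool that passed 26/33 BED3, 31/40 BED4 and 9/13 BED6 cases gets badges
reading `78.8%`, `77.5%` and `69.2%`:

```r
scores <- data.frame(variant = c(3, 4, 6),
                     expected_count = c(26, 31, 9),
                     total_count = c(33, 40, 13),
                     proportion = c(26/33, 31/40, 9/13))
make_badges(scores, dir = "badges")[, c("label", "value")]
#>        label          value
#> 1 BED parser BED3 BED4 BED6
#> 2       BED3          78.8%
#> 3       BED4          77.5%
#> 4       BED6          69.2%
```

## Command line

The installed package ships a CLI (`<library>/bedcert/exec/bedcert`):

```sh
bedcert validate intervals.bed --dialect flexible        # exit 0/1/2
bedcert corpus   --out corpus/
bedcert run      --config tools.yaml --corpus corpus/ --out results.tsv
bedcert fuzz     --tool-a mytool --tool-b reference \
                 --config tools.yaml --trials 500 --seed 7 --out fuzz/
bedcert badge    --results results.tsv --out badges/
```

The YAML configuration has three sections — `settings` (paths substituted
into command lines), `tools` (name → invocation template containing the
literal `FILE`, replaced per test case) and `conda-environment` (name →
environment label).

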