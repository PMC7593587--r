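---
title: "Detecting genetic code expansion in bacterial genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genetic code expansion in bacterial genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Some gut bacteria metabolise trimethylamine (TMA) using a methyltransferase
whose gene contains an in-frame TAG (amber) stop codon. The codon is not a
terminator: it is translated as the 22nd amino acid, pyrrolysine (one-letter
symbol `O`), by a dedicated tRNA with a CUA anticodon and a split
pyrrolysyl-tRNA synthetase. Standard gene callers truncate such genes at the
TAG, so the pathway is systematically misannotated in public assemblies. A
parallel recoding system inserts selenocysteine (`U`) at in-frame TGA (opal)
codons, directed by a SECIS stem-loop immediately downstream of the recoded
codon.

`gcescan` re-implements the detection procedure as a reusable, fully offline
pipeline:

1. **First pass** — ordinary ORF calling under the standard bacterial code
   (stops TAA/TAG/TGA, starts ATG/GTG/TTG) and classification of the
   predicted proteins against a packaged reference set for the
   pyrrolysine/selenocysteine/TMA pathway.
2. **Conditional second pass** — only when the pyrrolysine biosynthesis
   enzymes PylB, PylC and PylD are all present, prediction is repeated under
   a custom translation table in which TAG is a readthrough codon emitting
   `O`. Every first-pass gene terminated by TAG is extended through the
   codon to the next hard stop.
3. **Conservation filter** — a candidate recoded gene is accepted only when
   the sequence following the repurposed codon is conserved against the
   reference protein carrying pyrrolysine at a similar position. This
   replaces a manual inspection step with an explicit, testable rule.
4. **RNA elements** — a deterministic cloverleaf scan locates candidate
   Pyl-tRNAs (CTA anticodon) and Sec-tRNAs (TCA anticodon, long variable
   arm); a hairpin scan locates SECIS-like stem-loops downstream of
   in-frame TGA codons.
5. **Verdict** — a genome is `complete` when pylB, pylC, pylD, both
   synthetase genes, a Pyl-tRNA and a conserved TAG recoding in the TMA
   methyltransferase are all found; `partial` when some but not all are;
   `negative` otherwise.
6. **Expression screen** — independently of the genome analysis,
   transcripts are six-frame translated readthrough-aware and aligned
   locally to the reference proteins; expression is called at a minimum of
   98% amino-acid identity (a value at exactly 98.0 passes).

Everything runs on synthetic genomes and transcripts generated in-package
with a ground-truth manifest, so every stage is testable without network
access or external tools.

## Translation tables

Tables are plain-text files mapping all 64 codons; stop, readthrough and
coding roles must partition the codon space, which is asserted at load.
Three are packaged: `bact11` (the standard bacterial code), `pyl_readthrough`
(TAG removed from the stop set and mapped to `O`) and `sec_readthrough`
(TGA mapped to `U`). A codon containing `N` translates to `X` rather than
being skipped, so residue counts always equal the codons consumed. Lowercase
and RNA (`U`) input are normalised on ingest; internal start codons are not
forced to methionine, mirroring standard prokaryotic translation of
non-initiator positions.

## ORF model

The scanner is deterministic: every maximal start-to-stop ORF on both
strands, with the longest ORF kept per (strand, frame, terminator) — i.e.
the earliest start after the previous in-frame stop. It deliberately does
not model ribosome binding sites, start-site scores or GC frame bias: on
synthetic genomes with known gene boundaries a statistical gene finder adds
noise, not power, and the simple model is checkable against an exhaustive
brute-force oracle (which the tests do, on random contigs). `min_aa`
defaults to 50 residues. Coordinates are 0-based half-open on the forward
strand everywhere in the package; only the GFF3 writer converts to 1-based
closed.

The readthrough extension consumes at most `max_events` repurposed codons
per gene (default 1, configurable): a single conserved amber position per
TMA methyltransferase is the expected biology, and allowing longer chains
by default would let low-complexity regions concatenate genes. When the
budget is exhausted, the next readthrough codon terminates the gene.

## Homology and conservation

Pairwise protein alignment uses affine-gap dynamic programming (BLOSUM62,
gap open 11, extend 1; a gap of length L costs `11 + L`). The matrix is
extended so `O` and `U` score +5 against themselves and −4 against
everything else: a recoded site is rewarded only when both sequences carry
the noncanonical residue. Identity is computed over aligned columns
excluding end gaps; coverage is relative to the reference length. For
global alignments the two sequences are aligned in a canonical internal
order so that reported identity is symmetric even when co-optimal
alignments exist.

Classification assigns each predicted protein to at most one reference (its
top-scoring one; ties by identity, then reference order) and calls a
pathway component present when the best hit clears the per-component
identity and coverage thresholds (defaults 35% / 70%). This replaces a
profile-HMM search with top-hits-only semantics; an E-value cutoff has no
direct analogue under pairwise alignment and is documented as replaced, not
emulated.

The conservation rule aligns the 50 residues after the repurposed codon
(fewer if the gene ends) against the corresponding reference segment and
requires 40% identity. Both numbers are explicit package defaults, not
literature constants: 40% sits far above the ~6–10% identity expected for
random sequence under this scoring, and far below the near-identity of true
homologues, so the rule is insensitive to the exact value; the tests probe
both sides. A gene ending exactly at the recoded codon yields a degenerate,
non-conserved report rather than an error.

## tRNA scanning and the false-positive budget

The scanner uses a parametric cloverleaf template: acceptor stem 7 bp,
D stem 4 bp with a 4–11 nt loop, anticodon stem 5 bp with a 7 nt loop
(anticodon centred), a 0–23 nt variable arm, T stem 5 bp with a 7 nt loop,
and a discriminator base — total length 60 + D-loop + variable arm,
constrained to ≥ 70 nt. Pairing is Watson–Crick plus G·U wobble. A hit
requires per-arm paired-base minima (6/7, 3/4, 4/5, 4/5), the conserved
identity bases U33 (immediately 5′ of the anticodon) and the T-loop
T54-T55-C56 motif, and a total of at least 19 of 21 paired bases.

The stringency is a designed budget, not a fit. With per-bp pairing
probability 6/16 on random sequence, the per-arm minima alone admit roughly
10⁻⁵ of anticodon-anchored windows — but one megabase of random sequence
offers ~6 × 10⁴ anchors × ~10² spacer geometries ≈ 10⁷ trials, i.e. tens
of false hits. The two conserved-base checks (factor 1/256) and the
19/21 floor (factor ~7 × 10⁻⁷ instead of ~10⁻⁵) bring the expectation to
~0.02 false hits per Mb, which the tests verify as zero on a fixed 1-Mb
random sequence, cross-checked against an exhaustive all-window oracle on a
10-kb slice (the naive oracle is quadratic in practice; the slice keeps the
suite fast while still exercising every window/geometry combination).
Overlapping hits are collapsed best-score-first so that no two reported
hits overlap by more than half the shorter one. Selenocysteine tRNAs are
distinguished from pyrrolysine tRNAs by anticodon (TCA vs CTA) and the long
"extra arm" (variable arm ≥ 10 nt).

The SECIS model is likewise a stand-in for full thermodynamic folding:
the best hairpin is the longest perfectly paired stem (G·U allowed,
stem ≥ 7 bp, loop 3–12 nt) starting within 15 nt of the TGA 3′ end, ties
broken toward smaller offset then smaller loop. An opal recoding event is
reported only with classification, conservation and a SECIS hit in
agreement.

## Synthetic data: what it emulates, and what it does not

The generator emits i.i.d. background sequence at a target GC fraction with
pathway genes implanted at known coordinates on random strands. Implants
are back-translations of the packaged reference proteins with uniform
synonymous codon choice; recoded sites back-translate to TAG/TGA. Each
implant is flanked by a 12-nt insulator (`TTAATTAATTAA`, its own reverse
complement) containing stops in all six frames, so the first-pass caller
starts exactly at the implant's start codon and the manifest's recoded
codon index is exact rather than approximate. Three presets define the
study conditions: `pyl_complete` (the full pathway, both tRNAs, the recoded
TMA methyltransferase and selenoprotein, plus a methyltransferase-like
decoy without an in-frame TAG), `pyl_no_trna` (the same minus the Pyl-tRNA,
reproducing the known exception pattern of an otherwise complete genome
missing only its tRNA) and `negative` (decoys only). Defaults: 60 kb, GC
0.5, implant divergence 0% — detection correctness is tested exactly, and
divergence is a separate knob for sensitivity studies.

The packaged reference proteins are synthetic stand-ins generated once from
a fixed seed (`data-raw/make_reference_set.R`) and versioned with the
package; they are not derived from any real organism's sequence. The
selenoprotein CDS is designed, not free back-translated, because a perfect
8-bp hairpin 2 nt after the in-frame TGA cannot be guaranteed under random
synonymous codon choice.

Transcripts are back-translated 100-residue windows of the (optionally
mutated) implant proteins, placed on a random strand and frame recorded in
the manifest. The mutation model substitutes each site independently with
probability d/100 by a uniformly chosen different canonical residue,
leaving `O`/`U` untouched. None of this models sequencing error, indels,
coverage variation, chimeric assembly or community composition — so a
passing suite demonstrates the correctness of the detection logic, not
performance on real metatranscriptomes. In particular the 98% identity
threshold interacts with real data through assembly quality in ways the
simulation does not probe.

## Numerical and procedural choices

* Problem sizes in the test suite (20 × 2-kb ORF-oracle contigs, 100
  alignment-oracle pairs ≤ 60 aa, 20 genome seeds for ground-truth
  recovery, ~200 transcripts per divergence level, 1 Mb scanner
  specificity) were chosen to exercise each property at scale while keeping
  the default suite in the minutes range on one CPU.
* All generators draw from a single explicitly seeded stream per operation
  and restore the caller's RNG state; outputs are byte-identical across
  runs, which the tests assert.
* Tie-breaks are deterministic everywhere: longest ORF per terminator;
  top-scoring spec then identity then spec order in classification;
  best-score-first collapse in the tRNA scan; longest stem, then smallest
  offset, then smallest loop for SECIS.
* Degenerate inputs are contracts, not crashes: empty FASTA and malformed
  records raise errors naming the record; transcripts under 30 nt are
  skipped with a greppable warning; ORF extension off the contig edge keeps
  the candidate with a 3′-partial flag.

## Known limitations

The ORF scanner has no model for genes without an in-frame upstream stop
insulator, so on real assemblies start positions can be upstream of the
true start (the recoded codon index is then relative to the called start).
The tRNA scanner's fixed stem lengths and 19/21 floor are tuned for
specificity and will miss structurally atypical tRNAs that a covariance
model would find. The SECIS rule ignores thermodynamics and loop sequence.
The expression screen consumes assembled transcripts; read mapping,
co-assembly and quantification are out of scope.
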