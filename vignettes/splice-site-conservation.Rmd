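---
title: "Splice-site conservation analysis: models, conventions and design"
author: "spliceshare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splice-site conservation analysis: models, conventions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceshare)
```

## The question the package addresses

Spliceosomal introns are gained and lost slowly enough that an intron
sitting at *exactly* the same position of two orthologous coding sequences
is strong evidence that both genes inherited it from a common ancestor.
This logic is routinely used to decide whether gene families that look
alike at the protein level really share ancestry — for example whether the
two glycosyl-hydrolase-family-6 (GH6) domain genes found in tunicate
genomes (the free-standing *GH6-1* gene and the GH6 domain fused to
cellulose synthase, *CesA*) descend from one horizontally acquired gene or
from two. `spliceshare` implements the computation behind that argument:
it derives coding-exon splice sites, registers them on a protein multiple
alignment, and classifies which sites are shared, absent, or shifted by a
single nucleotide.

"Exactly the same position" has to be made precise, because exons end at
nucleotide resolution while alignments are built at residue resolution.
The package uses the residue/frame convention common in the tunicate
cellulose-synthase literature: an exon boundary is labelled by the protein
residue whose codon contains the exon's **last** nucleotide, plus the
codon position (frame `+1`, `+2`, `+3`) of that nucleotide. Writing $k$
for the boundary's coding-nucleotide offset (1-based index of the exon's
last nucleotide in the CDS),

$$\text{protein\_index} = \lceil k / 3 \rceil, \qquad
  \text{frame} = k - 3\,(\text{protein\_index} - 1),$$

so `V217.frame+2` means "the exon ends at the second codon position of
residue 217, a valine". The more widespread intron *phase* notation (0, 1,
2 = intron falls between codons, after the first, after the second
nucleotide) maps to frames `+3`, `+1`, `+2` respectively. Two sites from
different proteins are **shared** when they occupy the same alignment
column with the same frame; same column with a one-nucleotide offset is
*intron sliding* and is deliberately not counted as shared.

## Deriving sites and mapping transcripts

`derive_coding_splice_sites()` applies the formula above to each internal
boundary of a `gene_model` (a strand-aware chain of coding exons in
transcription order; GFF3 1-based inclusive coordinates throughout).
Models must be complete start-to-stop coding regions: partial fragments
would silently shift every residue index, so they are rejected rather
than guessed at. A boundary falling inside the terminal stop codon is
legal but lies outside protein-index space; it is reported as
`protein length + 1` with residue `*` and a warning.

When gene structures are not annotated, `map_cds_to_genome()` reconstructs
them from a coding transcript and the genomic region. It is an
**exact-match spliced mapper**: it finds the exon chain that reproduces
the CDS exactly after excising introns that are at least `min_intron`
nucleotides long and flanked GT..AG (optionally GC..AG). This is the
appropriate model for curated gene regions and simulated data; it is not
a spliced aligner and makes no attempt to handle sequencing errors,
frameshifts or trans-splicing. Degenerate inputs are handled by explicit
policy rather than silently:

* no consistent chain → an error, never a best-effort guess;
* several consistent chains (the intron's flanks happen to be repeated in
  the adjacent exon) → the chain opening each intron at the leftmost
  genomic position is returned, preferring the shortest intron on a tied
  start, and the model is flagged `ambiguous` with a warning.

The mapper is verified in the test suite against brute-force enumeration
of every split point on one- and two-intron toy genes.

## Registering sites on an alignment and classifying them

`project_sites()` lifts each site to the alignment column of its residue
(`residue_to_column()`), cross-checking the stored residue against the
alignment row so that a wrong alignment/protein pairing fails loudly.
A boundary after a codon's third nucleotide belongs to that codon's own
residue column, not the next residue — this keeps labels like `K316, +3`
attached to the residue the literature attaches them to.

`classify_site_groups()` partitions the calls into equivalence classes of
(column, frame). For each protein absent from a group it assigns one of
three statuses. *Shifted-by-one*: the protein has a site whose unrolled
nucleotide distance from the group site is exactly 1. The distance places
each column on a three-slot codon grid, $d = |3(c_a-1)+f_a -
(3(c_b-1)+f_b)|$, after deleting columns gapped in **both** rows of the
pair — the distance should reflect the two sequences' mutual alignment,
not gaps forced by third-party rows. Whether published one-nucleotide
shift calls were made on an unrolled nucleotide alignment or by frame
adjacency is not documented anywhere we know of; both conventions agree
on all cases handled here, and the both-gap-deletion rule is our
documented choice. *No site, conserved residue* versus *no site,
non-conserved residue*: decided by comparing the protein's residue at the
group column with the majority residue of the group members; ties count
as non-conserved. This majority rule is likewise our own explicit
criterion — the published tables annotate conservation without stating
one. The shift window defaults to exactly 1 nt; a wider "intron sliding"
window is available (`shift_window`) but off by default.

Group names follow the reference protein (first alignment row unless
overridden): three-letter prefix plus residue index, e.g. `Cin316`.
`render_site_table()` lays the groups out one row per protein with
`V217, +2` member cells, `n.s. (G285)` absences and `shifted (+2)` cells,
plus a per-protein intron count — the familiar shared-site matrix.
Membership never depends on residue identity: a column may legitimately
mix V, E, K, R and A while still being one ancestral intron position.

`synthetic_gh6_family()` ships a fully synthetic ten-gene family whose
documented residue indices and statuses reproduce the tunicate GH6-1 /
CesA shared-site matrix end to end (gene models with planted introns →
site derivation → projection → classification). Its scaffold alignment is
constructed so the documented residues co-occur in the documented
columns; it is test plumbing and illustration, not a reconstruction of
any published alignment.

## Sequence signatures and the catalytic residue

The PROSITE engine supports the core pattern grammar (fixed residues,
`x`, classes `[..]`, negated classes `{..}`, repeats `(n)`/`(n,m)`,
anchors `<`/`>`). `scan_sequence()` reports every overlapping match
start, resolving variable repeats greedily; it is tested against an
oracle that enumerates all repeat expansions. `score_signature_window()`
anchors a fixed-length pattern window on a chosen protein, lifts it to
columns, and counts satisfied positions per row — the "8–9 out of 10"
style of statement. Three deliberate choices:

* gaps in a scored window always count as mismatches (the window has a
  fixed length; skipping gaps would score a different, shorter window);
* an `X` in a sequence satisfies only `x` pattern elements — no wildcard
  credit against classes or negations;
* variable-repeat patterns are scannable but not window-scorable (there
  is no fixed window to score); this is an explicit error.

No PROSITE entries are bundled: patterns are user-supplied strings, so
the tool never embeds a possibly stale copy of an external database.
`catalytic_residue_check()` anchors one reference residue (for GH6, the
catalytic aspartate D221 of *Hypocrea jecorina* Cel6A) to its column and
reports, for every row, the residue found there, that protein's own
index (`E197`-style labels), and whether it matches the expected residue;
gapped rows are reported as `gap`, never counted as matches.

## The simulator: what it emulates, what it does not

`simulate_family()` generates an orthologous gene family with a fully
known intron history, so every pipeline stage can be checked against
exact truth. Defaults describe a tunicate-like setting: eight taxa on a
fixed tree in which two larvacean-like lineages branch first
(`default_family_tree()`), a 300-codon gene, five ancestral introns, and
intron lengths of 40–80 nt (comfortably above the 30-nt mapper minimum).
Evolution along each branch applies intron losses (per-intron survival
$e^{-\lambda\,t}$), intron gains (Poisson with rate per unit branch
length, or an exact scheduled count via `n_gains`/`n_losses` when an
experiment needs a fixed number of events), and per-site nucleotide
substitutions (probability $1 - e^{-\mu\,t}$), in cladewise branch order
with a single seeded generator, so runs are byte-reproducible from the
seed.

Three guardrails keep the truth labels crisp. Substitutions never touch
the start or stop codon and are resampled if they would create an
internal stop, so every simulated gene stays a valid complete CDS. New
intron offsets are drawn at least 4 nt away from every offset ever used
anywhere in the tree, so no two homology classes can collide or sit
within the one-nucleotide shift window of each other. And each emitted
genome is mapped back before being accepted: if the random intron
sequence happens to make the exact-match placement ambiguous, the intron
cores are resampled.

The default regime is **indel-free**, which makes the true protein
alignment the identity mapping (`identity_alignment()`); under it the
whole pipeline — genome emission, spliced mapping, site derivation,
projection, classification — recovers the simulated truth with precision
and recall 1.0, with or without substitutions, and `evaluate_recovery()`
scores that over (taxon, homology-class) membership pairs (an empty
prediction reports precision 1.0 with an explicit flag). This is a
strong correctness check of the machinery, but deliberately not a
realism claim: real data add alignment error, indels, non-canonical
splice sites, annotation noise and genuine intron sliding, none of which
the default simulation generates. A codon-multiple indel mode could be
layered on by supplying an external alignment, and the simulator makes no
attempt at realistic codon models (GY94 and kin), intron sequence
realism, or simulating the horizontal transfer event itself.

## Validation scale and reproducibility

The shipped tests run the worked labelling examples (650th and 948th
coding nucleotide → residues 217 and 316), the synthetic GH6 family
matrix, PROSITE scanning against the exhaustive oracle on 1,000 random
instances, mapper-versus-enumeration on ~500 toy genes, the
offset/residue/frame bijection and intron-insertion round trip on over
10,000 random cases, and full-pipeline recovery (F1 = 1.0) on twenty
seeded simulations with five ancestral introns, two gains, one loss and
substitution probability 0.05 — sizes chosen to give dense coverage while
keeping the whole suite comfortable on a laptop. `run_pipeline()` writes
every stage's table plus a summary JSON embedding a fingerprint of the
configuration, and identical configurations reproduce byte-identical
bundles.

## Known limitations

* The mapper requires the coding transcript to match the gene region
  exactly; diverged or error-containing transcripts need a real spliced
  aligner upstream, after which `parse_gff3()` can take over.
* Residue-conservation footnotes depend on the majority-residue rule
  described above; other conservation criteria (BLOSUM-positive,
  profile-based) would need to be scored externally.
* No statistical significance is attached to shared-site counts; the
  package reports the classification, not a p-value for convergent
  intron gain.
* Genomic co-location (`colocation_check()`) reports distance on a
  shared sequence only; it does not attempt synteny analysis across
  scaffolds.
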