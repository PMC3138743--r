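# rcmap — repeat conservation mapping of leucine-rich repeat domains

`rcmap` predicts candidate functional sites on leucine-rich repeat (LRR)
protein domains from sequence alone. It is written for people studying
LRR receptors and related repeat proteins — plant immune receptors such
as FLS2 and EFR, polygalacturonase inhibitors, Toll-like receptors,
ribonuclease inhibitor — who have two or more homologous sequences and
want to know *where on the domain surface* to aim mutagenesis or
interaction experiments, without waiting for a structure.

## The method

LRR domains are solenoids: each ~24-residue repeat is one helical turn,
the consensus residues (`xxLxxLxxLxxLxLxxNxLxGxIP`) are buried in the
core, and the variable `x` positions are solvent-exposed with predictable
relative spatial positions — position *p* of repeat *r* lies next to
position *p* of repeat *r* ± 1 on the surface. `rcmap` therefore:

1. detects repeats in a reference sequence against a consensus motif
   (with optional hand-curation of irregular repeats);
2. aligns the homologs (internally, or ingests a ClustalW/FASTA
   alignment) and maps every grid cell to its alignment column;
3. scores each cell's conservation over all homolog pairs — the raw mean
   substitution score, and the normalized ("weighted") score
   `w(a,b) = clip((S(a,b) − S_min) / (min(S(a,a), S(b,b)) − S_min), 0, 1)`
   which maps identity to 1 and the most dissimilar substitution to 0
   (BLOSUM62 by default, BLOSUM65 available);
4. smooths the weighted grid with a center-weighted 5×5 sliding window —
   25 cells spanning 5 repeats, ring weights 4/2/1 — into the **regional
   conservation score**, rendered as a red (conserved) to blue
   (divergent) heat map with the five beta-strand/beta-turn columns
   outlined;
5. optionally evaluates the map against annotated ligand-contact cells:
   decile enrichment per score stage and a one-sided pooled-variance
   Student's t-test of contact vs remaining scores.

A seeded synthetic-family generator with a known conserved patch makes
the whole pipeline testable end to end; see the methods vignette
(`vignettes/rcm-methods.Rmd`) for the model, parameter rationale and
limitations.

## Worked example

```r
library(rcmap)

fam <- generate_family(lrr_family_spec(seed = 42))  # 20 repeats, 4 sequences,
                                                    # background mutation 0.5,
                                                    # conserved 3x3 beta patch
fit <- rcm(fam, contacts = fam$patch)
fit
#> Repeat conservation map
#>   reference: syn01 (20 repeats, motif xxLxxLxxLxxLxLxxNxLxGxIP)
#>   family: 4 sequences; matrix blosum62; kernel default 5x5
#>   regional scores: 20 x 14 grid, range [0.442, 0.797]
#>   contact enrichment: 100% of 9 contacts in top decile (regional)

summary(fit)$top_cells
#>  repeat_index motif_position     score rank label
#>            10             13 0.7971044    1  10.3
#>            11             13 0.7804950    2  11.3
#>            10             11 0.7760136    3  10.2
#>             3              1 0.7667563    4   3:1
#>            10             15 0.7657308    5  10.4

fit$evaluation
#> top-decile fraction:     raw 0.333, weighted 1.000, regional 1.000
#> top-two-decile fraction: raw 1.000, weighted 1.000, regional 1.000
#> contact vs other (final stage): t = 8.832, one-sided p = 5.93e-17

plot(fit)                      # the heat map; write_rcm(fit, "out/") for
                               # TSVs, PNG and a re-runnable manifest
```

The top-ranked cells are exactly the planted conserved patch (labels
like `10.3` read "repeat 10, third beta-face position"), the decile
table shows contact capture improving from the raw to the weighted to
the regional stage, and the t-test confirms contacts score far above the
background — on real families with solved structures this is the
signature the method is validated by.

Real sequences work the same way: `rcm("family.fasta", motif = "plant",
reference = "FLS2", curation = read_curation("edits.tsv"))`. A thin CLI
over the same functions is at `inst/cli/rcm.R` (subcommands `map`,
`detect`, `simulate`, `eval`).

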