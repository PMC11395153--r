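# immunopepscore

Quality control and decision-tree prioritization of HLA class I
immunopeptidomes from LC-MS/MS identification tables.

After immunoprecipitating HLA-I complexes and searching the spectra, an
immunopeptidomics experiment leaves you with identification tables:
thousands of peptides with charge, m/z, ion mobility, protein assignments,
and -- for de novo identifications -- an average local confidence (ALC).
Most of those identifications are not plausible HLA-I ligands. This package
is for proteomics and immunology groups who need a reproducible way from
those tables to a short list of candidate immunopeptides.

## The Immunopeptidome Score

Each unique, non-contaminant peptide receives 0--3 points from a three-stage
decision tree with short-circuit dismissal:

| stage | criterion | point |
|---|---|---|
| 1. length | 8 ≤ L ≤ 12 residues (HLA-I groove window) | +1, else dismissed |
| 2. binding | strong predicted binder (%rank ≤ 0.5) for ≥ 1 class I allele of the sample | +1, else dismissed |
| 3. immunogenicity | predicted immunogenicity score > 0 | +1 |

Peptides scoring 3 are the selected set. Binding classes use the NetMHCpan
convention (strong ≤ 0.5% rank, weak ≤ 2% rank, inclusive); de novo
peptides are first filtered at ALC ≥ 80 and scored as a separate set.
Funnel reports give the percentage surviving each stage from 100% of the
unique identifications, plus the most restrictive stage.

Around the score, the package provides: PEAKS-style CSV readers and a
FASTA writer for predictor submission; NetMHCpan-4.1 and IEDB
class-I-immunogenicity output parsers (classes always recomputed from the
rank, never trusted from SB/WB annotations); deduplication and
contaminant removal; QC summaries (length/charge histograms, deterministic
two-group ion-mobility partition, CRAPome Ave SC ≤ 5 expected-protein
fraction); cross-sample Venn overlaps; deterministic stand-in predictors
for offline testing; and a synthetic identification-table generator with
planted ground truth.

## Worked example

```r
library(immunopepscore)

cfg <- synth_config(n_peptides = 2000, seed = 42)   # emulated LC-MS/MS table
sim <- generate_sample(cfg)
res <- run_immunopeptidome_score(sim$records, motifs = cfg$motifs,
                                 contaminants = cfg$contaminant_accessions,
                                 seed = 7)
res$db$funnel
#> # A tibble: 1 x 10
#>   sample_id        n_input_unique n_pass_length n_pass_binding
#> 1 synthetic_sample           1797          1413            435
#>   n_pass_immunogenicity pct_pass_length pct_pass_binding pct_selected
#>                     210            78.6             24.2         11.7
#>   most_restrictive_stage percentages_undefined
#> 1 binding                FALSE
```

Of 2000 identifications, 1797 database-search peptides remain after
removing contaminant-only rows and collapsing charge/modification
duplicates. 78.6% are 8--12-mers, 24.2% additionally have a strong
predicted binder among the three configured alleles, and 11.7% also score
positive immunogenicity -- the selected set (210 peptides, score 3):

```r
head(res$db$scores[res$db$scores$final_score == 3, ], 3)
#>   bare_sequence stage1_length stage2_binding stage3_immunogenicity final_score
#> 1 PLLAAFMGE                 1              1                     1           3
#> 2 LRLMVIVGG                 1              1                     1           3
#> 3 VCLFGALAF                 1              1                     1           3
```

With real data, replace the stand-in motifs by adapter files:

```r
records <- read_peptide_table("peptides.csv", dialect = "peaks_db")
binding <- read_netmhcpan_output("netmhcpan_out.txt")   # text or TSV
immuno  <- read_immunogenicity_output("iedb_out.csv")
crap    <- read_contaminant_table("contaminants.txt", "accession_list")
res <- run_immunopeptidome_score(records, binding = binding,
                                 immuno = immuno, contaminants = crap)
```

A thin command-line front end with `simulate`, `qc`, `score` and `compare`
subcommands is installed at
`system.file("cli", "immunopepscore.R", package = "immunopepscore")`.

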