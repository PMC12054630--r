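# anchorseek

Cross-species anchor-gene correlation screening for single-cell
transcriptomics, with the downstream phenotype-association and promoter
analyses that typically follow such a screen.

## The scientific problem

Stressed cardiomyocytes in the failing heart re-express foetal genes, with
*Nppa* (atrial natriuretic peptide) the canonical marker. Genes whose
single-cell expression correlates with *Nppa* within cardiomyocytes are
candidates for the cardiomyocyte stress program — and a candidate found
independently in both a mouse disease model and human heart-failure tissue
is unlikely to be a dataset artifact. anchorseek implements this screen as
a reusable pipeline:

- per species: QC filter → CP10K `log1p` normalization → Spearman
  correlation of every gene with the anchor across the chosen cell type →
  top-K list (K = 50);
- across species: transport the top list through an explicit homolog table
  (many-to-many) and intersect with the other species' top list;
- validation: two-sided Wilcoxon rank-sum stress-response test per
  candidate with Benjamini–Hochberg adjustment;
- phenotype association: pairwise Spearman correlations against clinical
  covariates, an equal-weights collagen composite score
  ((Col1a1 + Col1a2 + Col3a1)/3), and a univariable → multivariable linear
  regression cascade (keep covariates with univariable *p* < 0.05, then
  backward-eliminate in the joint model until all retained covariates have
  *p* < 0.05);
- promoter tools: 1-based inclusive interval arithmetic and GATA-motif
  scanning (IUPAC consensus `WGATAA` or any user-supplied PWM, both
  strands, log2-odds in bits).

The core statistic is Spearman's rank correlation
$\rho = \mathrm{cor}(\mathrm{rank}\,x, \mathrm{rank}\,y)$, chosen because it
is invariant to the log base of the normalization and robust in sparse
data; the Wilcoxon test and BH step-up carry the same rank-based,
assumption-light philosophy into validation.

A synthetic-data module (`simulate_pair()`, `simulate_clinical()`)
generates paired-species negative-binomial count data with a planted
anchor-correlated program, a partial homolog map, and a clinical table with
known true covariates, so the whole pipeline is testable offline with
ground truth. See the methods vignette
(`vignettes/anchorseek-methods.Rmd`) for the generative model and every
numerical choice.

## Worked example

```r
library(anchorseek)

cfg <- sim_config(n_genes = 1000, n_cells_per_group = 200, n_planted = 25,
                  effect_size = 1, homolog_fraction = 0.9, seed = 42)
pair <- simulate_pair(cfg)
scr  <- anchor_screen(pair$a, pair$b, pair$homologs,
                      anchor_a = "Nppa", anchor_b = "NPPA", k = 50)

scr$mapping$n_mappable     # mouse top-50 genes with a known homolog
#> [1] 40
head(scr$conserved, 5)     # genes in both species' top-50, both ranks shown
#>     gene_b   gene_a rank_a rank_b
#> 1 GENE0014 gene0014      8      1
#> 2 GENE0008 gene0008     11      3
#> 3 GENE0013 gene0013      9      6
#> 4 GENE0004 gene0004      6      7
#> 5 GENE0023 gene0023     25      9
mean(pair$truth$planted_genes$b %in% scr$conserved$gene_b)
#> [1] 0.76                 # recall of the planted program

stress_de(lognormalize(pair$b$counts), pair$b$meta,
          head(scr$conserved$gene_b, 3))
#>       gene    log2fc            p            q n_control n_stressed
#> 1 GENE0014 0.3294577 1.142153e-10 3.426458e-10       200        200
#> 2 GENE0008 0.3830584 1.126672e-09 1.690008e-09       200        200
#> 3 GENE0013 0.5138764 3.002681e-09 3.002681e-09       200        200

regression_cascade(simulate_clinical(cfg)$clinical)
#> regression cascade (alpha = 0.05)
#>   stage 1: 7/42 covariates significant
#>   retained:
#>  covariate      coef         se            p
#>      cov01 0.3634910 0.07263437 2.720533e-06
#>      cov02 0.2079615 0.06597677 2.195719e-03
#>      cov03 0.2698890 0.07067514 2.446712e-04

interval_length(parse_interval("chr8:46080750-46081200", assembly = "mm39"))
#> [1] 451                  # the promoter fragment spans 451 bp
scan_consensus("GGCTTGAGATAACCTGA")
#>   position strand   site score
#> 1        7      + AGATAA   1
```

Reading the output: 40 of the 50 top mouse genes had a homolog; 19 genes
sat in both species' top-50 after mapping, recovering 76% of the 25-gene
planted program; all shown candidates are significantly induced in
stressed cells (positive log2FC, tiny BH q); the clinical cascade retains
exactly the three covariates that were simulated as truly associated
(cov01–cov03); and the interval/motif helpers reproduce the 451 bp
promoter arithmetic and find the GATA core site.

## Command line

Each stage is also a subcommand of the installed `exec/anchorseek` script:

```sh
anchorseek simulate  --config cfg.json --out DIR --seed 1
anchorseek qc        --in DIR --out DIR --min-counts 500 --min-genes 200
anchorseek correlate --in DIR --anchor Nppa --cell-type CM --out corr.tsv
anchorseek conserve  --corr-a corr_a.tsv --corr-b corr_b.tsv \
                     --homologs homologs.tsv --k 50 --out conserved.tsv
anchorseek de        --in DIR --genes conserved.tsv --out de.tsv
anchorseek pheno     --clinical clinical.tsv --target target_expr --out report/
anchorseek motif     --fasta seqs.fa --consensus WGATAA --out hits.tsv
```

Outputs are TSV plus a JSON run manifest (parameters, seed, versions).

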