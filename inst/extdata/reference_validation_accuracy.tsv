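scheme	fold	accuracy_pct
subject_subsets	1	88.73
subject_subsets	2	76.55
subject_subsets	3	81.28
subject_subsets	4	74.44
subject_subsets	5	85.06
subject_subsets	6	81.02
subject_subsets	7	83.58
subject_subsets	8	76.32
subject_subsets	9	88.29
subject_subsets	10	80.56
subject_subsets	11	75.13
subject_subsets	12	77.85
subject_subsets	13	72.39
subject_subsets	14	76.98
random_split	1	83.25
random_split	2	81.94
random_split	3	79.27
random_split	4	78.55
random_split	5	87.21
random_split	6	84.35
random_split	7	81.13
random_split	8	84.57
random_split	9	86.88
random_split	10	82.46
random_split	11	86.12
random_split	12	81.97
random_split	13	82.48
random_split	14	84.59
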