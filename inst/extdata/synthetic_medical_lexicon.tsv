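# Synthetic medical-term lexicon (term <TAB> weight).
# A constructed stand-in for a large medical terminology export, covering
# common oncology vocabulary in English and Spanish. Weights are roughly
# frequency-ranked; read_domain_lexicon() normalizes them to a distribution.
cancer	100
tumor	80
carcinoma	35
leukemia	60
lymphoma	40
metastasis	45
sarcoma	25
melanoma	55
skin cancer	50
chemotherapy	48
chemo	30
radiotherapy	22
homeopathy	18
oncology	28
oncologist	20
biopsy	24
malignant	26
benign	15
diagnosis	42
prognosis	16
remission	21
relapse	14
screening	27
mammogram	12
prostate	19
pancreatic	17
ovarian	13
cervical	11
colorectal	12
lung cancer	30
breast cancer	44
brain tumor	26
therapy	38
treatment	52
patient	46
patients	30
survivor	23
symptoms	31
disease	41
immunotherapy	16
clinical	25
trial	18
drug	29
cells	22
cell	20
gene	14
mutation	12
radiation	19
surgery	33
hospital	36
doctor	34
nurse	17
diagnosed	25
stage	21
cure	24
prevention	18
awareness	22
sunscreen	10
ultraviolet	8
cholesterol	26
ldl	14
mri	16
scan	15
blood	28
marrow	11
transplant	13
donor	9
vaccine	12
health	47
medicine	26
medical	31
pediatric	10
palliative	8
hospice	7
lesion	9
nodule	7
polyp	6
lump	11
fatigue	9
nausea	8
pain	20
risk	23
smoking	15
tobacco	9
obesity	8
genetic	11
hereditary	6
biomarker	5
pathology	8
recurrence	7
metastatic	13
inoperable	4
terminal	9
cáncer	70
tumor cerebral	18
leucemia	34
linfoma	16
metástasis	24
melanoma nodular	6
quimioterapia	28
radioterapia	12
homeopatía	10
oncólogo	11
biopsia	10
maligno	9
benigno	6
diagnóstico	21
cribado	5
mamografía	7
próstata	9
páncreas	8
pulmón	12
mama	22
cerebral	10
terapia	17
tratamiento	25
paciente	19
pacientes	13
superviviente	7
síntomas	12
enfermedad	20
ensayo	6
fármaco	11
células	9
radiación	7
cirugía	13
médico	16
enfermera	6
diagnosticado	8
etapa	5
curación	7
prevención	9
sanidad	6
salud	21
medicina	12
colesterol	11
sangre	10
médula	5
trasplante	6
vacuna	7
dolor	9
riesgo	10
tabaco	6
oración	3
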