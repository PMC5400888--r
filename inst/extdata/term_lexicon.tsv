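# term	category	semtype - synthetic term lexicon keyed by UMLS-style semantic types
cough	medical	sosy
pain	medical	sosy
breathless	medical	sosy
wheezing	medical	sosy
nausea	medical	sosy
fatigue	medical	sosy
thirsty	medical	sosy
tired	medical	sosy
dizzy	medical	sosy
itchy	medical	sosy
sore	medical	sosy
tingling	medical	sosy
chest pain	medical	sosy
shortness of breath	medical	sosy
hot flashes	medical	sosy
frequent urination	medical	sosy
nipple discharge	medical	sosy
hungry	medical	sosy
hoarseness	medical	sosy
night sweats	medical	sosy
weight loss	medical	sosy
loss of appetite	medical	sosy
numbness	medical	sosy
headache	medical	sosy
blurred vision	medical	sosy
dry mouth	medical	sosy
chills	medical	sosy
fever	medical	sosy
back pain	medical	sosy
joint pain	medical	sosy
palpitations	medical	sosy
sweating	medical	sosy
insomnia	medical	sosy
swollen ankles	medical	sosy
infection	medical	dsyn
bronchitis	medical	dsyn
pneumonia	medical	dsyn
tuberculosis	medical	dsyn
asthma	medical	dsyn
pleural effusion	medical	patf
copd	medical	dsyn
emphysema	medical	dsyn
atelectasis	medical	patf
hypoglycemia	medical	patf
obesity	medical	patf
kidney disease	medical	dsyn
diabetic neuropathy	medical	dsyn
rash	medical	dsyn
mastitis	medical	dsyn
eczema	medical	dsyn
neuropathy	medical	dsyn
lymph edema	medical	dsyn
complex cyst	medical	dsyn
coma	medical	dsyn
sepsis	medical	dsyn
anemia	medical	dsyn
dehydration	medical	dsyn
ketoacidosis	medical	dsyn
retinopathy	medical	dsyn
nephropathy	medical	dsyn
gastroparesis	medical	dsyn
cellulitis	medical	dsyn
pulmonary embolism	medical	dsyn
pleurisy	medical	dsyn
hypercalcemia	medical	dsyn
bone metastasis	medical	dsyn
brain metastasis	medical	dsyn
thrush	medical	dsyn
shingles	medical	dsyn
foot ulcers	medical	dsyn
biopsy	medical	diap
mri	medical	diap
ultrasound	medical	diap
mammogram	medical	diap
screening	medical	diap
x-ray	medical	diap
cat scan	medical	diap
pet scan	medical	diap
imaging	medical	diap
bronchoscopy	medical	diap
blood test	medical	lbpr
glucose test	medical	lbpr
fasting test	medical	lbpr
glucose tolerance test	medical	lbpr
hemoglobin a1c test	medical	lbpr
chest x-ray	medical	diap
core biopsy	medical	diap
fasting blood sugar	medical	lbpr
ct scan	medical	diap
bone scan	medical	diap
echocardiogram	medical	diap
spirometry	medical	diap
tumor marker test	medical	diap
cea test	medical	diap
c peptide test	medical	diap
microalbumin test	medical	diap
lipid panel	medical	diap
thyroid panel	medical	diap
liver panel	medical	diap
sputum cytology	medical	diap
fine needle aspiration	medical	diap
ekg	medical	diap
bone density scan	medical	diap
chemo	medical	topp
operation	medical	topp
surgery	medical	topp
radiation	medical	topp
therapy	medical	topp
chemotherapy	medical	topp
removal	medical	topp
radiation therapy	medical	topp
lobectomy	medical	topp
mastectomy	medical	topp
lumpectomy	medical	topp
infusion	medical	topp
injection	medical	topp
transplant	medical	topp
dialysis	medical	topp
insulin injection	medical	topp
amputation	medical	topp
wedge resection	medical	topp
radiotherapy	medical	topp
implant	medical	topp
port placement	medical	topp
stent placement	medical	topp
cryotherapy	medical	topp
brachytherapy	medical	topp
reconstruction	medical	topp
axillary dissection	medical	topp
oophorectomy	medical	topp
thoracentesis	medical	topp
pleurodesis	medical	topp
bypass surgery	medical	topp
laser therapy	medical	topp
physical therapy	medical	topp
insulin pump therapy	medical	topp
gastric bypass	medical	topp
insulin	medical	phsu
metformin	medical	phsu
lantus	medical	phsu
januvia	medical	phsu
glucophage	medical	phsu
actos	medical	phsu
avandia	medical	phsu
amaryl	medical	phsu
glipizide	medical	phsu
tamoxifen	medical	phsu
arimidex	medical	phsu
taxol	medical	phsu
femara	medical	phsu
taxotere	medical	phsu
carboplatin	medical	phsu
morphine	medical	phsu
advil	medical	phsu
tarceva	medical	phsu
chantix	medical	phsu
alimta	medical	phsu
dilaudid	medical	phsu
coumadin	medical	phsu
effexor	medical	phsu
docetaxel	medical	phsu
valium	medical	phsu
raloxifene	medical	phsu
gemcitabine	medical	phsu
cisplatin	medical	phsu
etoposide	medical	phsu
paclitaxel	medical	phsu
bevacizumab	medical	phsu
erlotinib	medical	phsu
gefitinib	medical	phsu
afatinib	medical	phsu
pemetrexed	medical	phsu
vinorelbine	medical	phsu
topotecan	medical	phsu
irinotecan	medical	phsu
capecitabine	medical	phsu
anastrozole	medical	phsu
letrozole	medical	phsu
exemestane	medical	phsu
fulvestrant	medical	phsu
trastuzumab	medical	phsu
lapatinib	medical	phsu
palbociclib	medical	phsu
glimepiride	medical	phsu
pioglitazone	medical	phsu
sitagliptin	medical	phsu
liraglutide	medical	phsu
exenatide	medical	phsu
canagliflozin	medical	phsu
dapagliflozin	medical	phsu
acarbose	medical	phsu
repaglinide	medical	phsu
gabapentin	medical	phsu
tramadol	medical	phsu
oxycodone	medical	phsu
prednisone	medical	phsu
husband	kinship	famg
wife	kinship	famg
mother	kinship	famg
father	kinship	famg
mom	kinship	famg
dad	kinship	famg
son	kinship	famg
daughter	kinship	famg
sister	kinship	famg
brother	kinship	famg
father in law	kinship	famg
mother in law	kinship	famg
grandmother	kinship	famg
aunt	kinship	famg
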