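peptide	mw	pi
A	89.0932	5.57
C	121.1582	5.5181
D	133.1027	4.2994
E	147.1293	4.5993
F	165.1891	5.525
G	75.0666	5.525
H	155.1546	6.7411
I	131.1729	5.525
K	146.1876	8.7501
L	131.1729	5.525
M	149.2113	5.275
N	132.1179	5.525
P	115.1305	5.955
Q	146.1445	5.525
R	174.201	9.75
S	105.0926	5.24
T	119.1192	5.185
V	117.1463	5.495
W	204.2252	5.525
Y	181.1885	5.5243
GG	132.1179	5.525
KKKKKKKKKK	1299.7383	10.9544
ACDEFGHIKLMNPQRSTVWY	2395.7134	6.7846
TSPEDHKQGPSS	1269.275	5.2904
VIMTSNRIVQYH	1460.6997	8.7258
CFNRWVYDLKGH	1537.7423	8.2063
ILHIDITKCDSA	1328.5341	5.2106
SKQRDWRVPLWHSDLAGSGSLRDYL	2943.2347	8.3321
SCKFYLDEQNLQDTDHVKFRKNGAQ	2985.2465	6.4753
KEYQRYAETVCTLLYYHSHHSWDMK	3189.5362	7.0122
TECHLYTCRNNYNIKCLHSETDYIQ	3062.372	5.9438
HEVKVWYPNWEIPSVKNSFGQREAYFSGESGDCVNCYRDI	4711.1218	5.0077
AREEFEDWIDGDHLFVMHMHFMGRDSLTFKDVHGVCHTSG	4691.1818	5.2293
QPSTCKNHTSKVFIKKQKWECETGSNWRNTAAADLYWRCQ	4745.2976	9.3045
LCKRTNHRGFPAYMEEHYIEPCKMYAFIILHENFMNARKT	4904.697	8.7593
HFVCCVHWRGIRPHSKPWDNILCEEGNRLRKIQLGGCRGKSIMIMCKDQWCNFRIDLTRF	7203.4626	9.3775
FKMYIPSKHPTWTTQNSQGNDLAVISITNGPMSLTHLGYYHDLQYFNEANGNFNGQGIVK	6760.4507	7.0198
QNRENDDYPRDNPEGKRTDKFRLQTVHGSSWQKAEQGDFGSEFYICCIKNHHKTVFEKEN	7159.6898	6.3102
KAMYTFHSLMLHVIYVRLIKIPMPQTQVGNDQRSNFCALPEDSWLNILLRGFVDEGPIST	6905.9964	6.9169
RSWCTWDFCCKEDYRTPRICPFGHFHVYNNWALLVMDYHWRRVIHLSMFTFGHKKRVQNQ	7562.6663	9.384
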