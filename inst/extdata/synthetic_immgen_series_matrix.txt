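!Series_title	"Synthetic stand-in for an ImmGen Phase 1 thymocyte subset (fixture; not real GEO data)"
!Series_geo_accession	"GSE00000"
!Sample_title	"T.DN4.Th#1"	"T.DN4.Th#2"	"T.DN4.Th#3"	"T.DP.Th#1"	"T.DP.Th#2"	"T.DP.Th#3"	"T.DP69+.Th#1"	"T.DP69+.Th#2"	"T.DP69+.Th#3"
!Sample_geo_accession	"GSM00001"	"GSM00002"	"GSM00003"	"GSM00004"	"GSM00005"	"GSM00006"	"GSM00007"	"GSM00008"	"GSM00009"
!series_matrix_table_begin
"ID_REF"	"GSM00001"	"GSM00002"	"GSM00003"	"GSM00004"	"GSM00005"	"GSM00006"	"GSM00007"	"GSM00008"	"GSM00009"
"Themis"	301.0	295.4	302.2	1529.6	1502.1	1528.0	402.7	396.7	397.7
"Clk3"	789.6	801.6	800.2	1975.5	2011.0	2015.0	703.9	696.0	688.9
"Slc6a19"	19.7	19.7	19.8	295.0	303.9	301.1	25.3	24.9	24.5
"Wdr78"	30.4	29.4	29.6	250.0	248.2	248.5	40.1	39.3	39.9
"Rag1"	100.8	101.3	100.4	3057.3	3043.7	2997.9	151.6	152.6	149.9
"Rag2"	122.0	119.4	119.6	2809.9	2756.4	2823.5	131.7	131.3	132.5
"Actb"	4958.5	5070.9	4917.1	5210.3	5287.2	5176.8	5184.7	5056.6	5135.4
"Cd69"	50.5	49.9	50.7	60.1	61.0	58.8	2027.3	1966.9	2010.8
"Sell_p1"	897.2	896.8	901.0	393.4	400.6	393.9	603.0	605.4	601.3
"Sell_p2"	885.2	864.0	882.6	418.2	414.0	412.6	605.5	599.8	617.9
"Cd4"	98.3	101.4	98.7	2499.1	2469.3	2471.4	2646.9	2598.5	2593.6
"Il7r"	686.5	687.6	708.7	908.4	885.2	904.7	302.3	298.1	301.1
!series_matrix_table_end
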